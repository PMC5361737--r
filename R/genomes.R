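#' A labelled reference genome
#'
#' A small container pairing a set of chromosome sequences with a role
#' label: `"target"` for the genome being assayed or `"spikein"` for the
#' exogenous reference genome added for quantification.
#'
#' @param label Either `"target"` or `"spikein"`.
#' @param seqs A named character vector or [Biostrings::DNAStringSet] of
#'   chromosome sequences over the ACGT alphabet.
#' @param marked_loci Optional data.frame of ground-truth marked loci with
#'   columns `chrom`, `start`, `end` (0-based half-open). Simulation-only.
#' @return An object of class `ReferenceGenome`.
#' @export
reference_genome <- function(label, seqs, marked_loci = NULL) {
  label <- match.arg(label, c("target", "spikein"))
  if (!methods::is(seqs, "DNAStringSet")) {
    seqs <- Biostrings::DNAStringSet(seqs)
  }
  nm <- names(seqs)
  if (is.null(nm) || anyNA(nm) || any(nm == "") || anyDuplicated(nm)) {
    stop("chromosome names must be present and unique")
  }
  if (any(Biostrings::width(seqs) == 0)) stop("all sequences must be non-empty")
  freq <- Biostrings::alphabetFrequency(seqs, baseOnly = TRUE)
  if (any(freq[, "other"] > 0)) {
    stop("sequences must be restricted to the A/C/G/T alphabet")
  }
  obj <- list(label = label, seqs = seqs, marked_loci = marked_loci)
  class(obj) <- "ReferenceGenome"
  obj
}

#' @export
print.ReferenceGenome <- function(x, ...) {
  cat(sprintf("ReferenceGenome [%s]: %d chromosome(s), %d bp total\n",
              x$label, length(x$seqs), sum(Biostrings::width(x$seqs))))
  if (!is.null(x$marked_loci)) {
    cat(sprintf("  %d ground-truth marked loci\n", nrow(x$marked_loci)))
  }
  invisible(x)
}

genome_length <- function(genome) sum(Biostrings::width(genome$seqs))

#' Build a pair of toy genomes for simulation
#'
#' Generates independent random target and spike-in genomes (one chromosome
#' each, iid uniform ACGT) and plants non-overlapping marked loci in each.
#' Because the two genomes are drawn independently, cross-genome exact
#' matches at read length are vanishingly rare, which is what makes
#' unique-mapping genome attribution essentially error-free downstream.
#'
#' Loci are placed one per equal-width slot, uniformly within the slot, so
#' they can never overlap. Ground-truth locus coordinates are stored on each
#' genome (0-based half-open, BED convention).
#'
#' @param config A [sim_config()] object.
#' @return A named list with elements `target` and `spikein`, both
#'   `ReferenceGenome`s carrying their `marked_loci` truth tables.
#' @export
#' @examples
#' g <- build_toy_genomes(sim_config(seed = 1))
#' g$target
build_toy_genomes <- function(config) {
  validate_config(config)
  if (config$target_genome_size <= 10 * config$locus_width ||
      config$spikein_genome_size <= 10 * config$locus_width) {
    stop("genome size too small: must exceed 10 x locus_width")
  }
  set.seed(config$seed)
  target <- random_genome("chr1", config$target_genome_size,
                          config$n_marked_loci_target, config$locus_width,
                          "target")
  spikein <- random_genome("sf_contig1", config$spikein_genome_size,
                           config$n_marked_loci_spikein, config$locus_width,
                           "spikein")
  list(target = target, spikein = spikein)
}

random_genome <- function(chrom, size, n_loci, locus_width, label) {
  seq <- paste(sample(c("A", "C", "G", "T"), size, replace = TRUE),
               collapse = "")
  loci <- place_loci(chrom, size, n_loci, locus_width)
  reference_genome(label, stats::setNames(seq, chrom), marked_loci = loci)
}

# One locus per equal slot guarantees non-overlap; errors if slots are too
# narrow for the requested width.
place_loci <- function(chrom, size, n_loci, locus_width) {
  if (n_loci == 0) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer()))
  }
  slot <- floor(size / n_loci)
  if (slot < locus_width) {
    stop(sprintf(
      "genome of %d bp cannot hold %d non-overlapping loci of %d bp",
      size, n_loci, locus_width))
  }
  offset <- floor(stats::runif(n_loci, 0, slot - locus_width + 1))
  start <- as.integer((seq_len(n_loci) - 1L) * slot + offset)
  data.frame(chrom = chrom, start = start,
             end = start + as.integer(locus_width))
}

#' Write / read genomes as FASTA
#'
#' @param genome A `ReferenceGenome`.
#' @param path Output FASTA path.
#' @return `write_genome_fasta` returns `path` invisibly;
#'   `read_genome_fasta` returns a `ReferenceGenome` (without truth loci).
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome$seqs, path)
  invisible(path)
}

#' @rdname write_genome_fasta
#' @param label Genome label to attach on read.
#' @export
read_genome_fasta <- function(path, label) {
  reference_genome(label, Biostrings::readDNAStringSet(path))
}

#' Write ground-truth marked loci as BED6
#' @param genome A `ReferenceGenome` with a `marked_loci` table.
#' @param path Output BED path.
#' @export
write_truth_bed <- function(genome, path) {
  loci <- genome$marked_loci
  if (is.null(loci)) stop("genome carries no ground-truth loci")
  lines <- sprintf("%s\t%d\t%d\tlocus%04d\t0\t.",
                   loci$chrom, loci$start, loci$end, seq_len(nrow(loci)))
  writeLines(lines, path)
  invisible(path)
}
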