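#' Simulate a synthetic ChIP-Rx experiment
#'
#' Draws four sequencing libraries (pulldown and input, for a treated and a
#' vehicle condition) from a two-species chromatin pool. The pool's
#' genome-of-origin proportions follow cell numbers weighted by genome
#' length, so with equal genome lengths and the default 1e7:3e6 cell mix
#' the expected spike-in fragment fraction is 3/13. Input libraries sample
#' fragments uniformly from the pool; pulldown libraries capture a fragment
#' overlapping a marked locus with probability
#' `min(1, pulldown_efficiency * occupancy)` and an unmarked fragment with
#' probability `background_capture`. Occupancy is `base_occupancy`
#' everywhere except target loci in the treated condition, where it is
#' multiplied by `fold_change`; spike-in occupancy is identical across
#' conditions, which is the assumption that makes spike-in scaling a valid
#' yardstick.
#'
#' Reads are the first `read_length` bases of each captured fragment, taken
#' from a uniformly chosen strand (plus the mate from the other end when
#' `paired = TRUE`). All randomness descends from `config$seed`; identical
#' configs give byte-identical libraries.
#'
#' @param config A [sim_config()].
#' @param genomes The pair returned by [build_toy_genomes()] (or any list
#'   with `target` and `spikein` `ReferenceGenome`s carrying truth loci).
#' @return A list of four `SampleLibrary` objects named
#'   `pulldown_treated`, `pulldown_vehicle`, `input_treated`,
#'   `input_vehicle`.
#' @export
#' @examples
#' cfg <- sim_config(seed = 7, depth = 500)
#' libs <- simulate_chiprx_experiment(cfg, build_toy_genomes(cfg))
#' libs$input_vehicle
simulate_chiprx_experiment <- function(config, genomes) {
  validate_config(config)
  if (config$depth == 0) {
    warning("depth = 0: simulating empty libraries")
  }
  plan <- data.frame(
    sample_id = c("pulldown_treated", "pulldown_vehicle",
                  "input_treated", "input_vehicle"),
    role = c("pulldown", "pulldown", "input", "input"),
    condition = c("treated", "vehicle", "treated", "vehicle"),
    stringsAsFactors = FALSE
  )
  libs <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    set.seed(config$seed + i)
    libs[[i]] <- simulate_library(plan$sample_id[i], plan$role[i],
                                  plan$condition[i], config, genomes)
  }
  stats::setNames(libs, plan$sample_id)
}

#' @export
print.SampleLibrary <- function(x, ...) {
  cat(sprintf("SampleLibrary %s (%s, %s): %d reads\n",
              x$sample_id, x$role, x$condition, nrow(x$reads)))
  invisible(x)
}

simulate_library <- function(sample_id, role, condition, config, genomes) {
  depth <- config$depth
  frags <- if (depth == 0) {
    empty_fragments()
  } else if (role == "input") {
    draw_fragments(depth, config, genomes)
  } else {
    sample_pulldown_fragments(depth, condition, config, genomes)
  }
  reads <- fragments_to_reads(frags, sample_id, config, genomes)
  structure(list(sample_id = sample_id, role = role, condition = condition,
                 reads = reads),
            class = "SampleLibrary")
}

empty_fragments <- function() {
  data.frame(genome = character(), chrom = character(), start = integer(),
             fraglen = integer(), marked = logical())
}

# Draw n fragments from the chromatin pool. Genome of origin is Bernoulli
# with probability proportional to cells x genome length; position uniform
# within the chosen chromosome; lengths Normal(mean, sd) truncated below at
# read_length and clamped to the chromosome.
draw_fragments <- function(n, config, genomes) {
  lt <- genome_length(genomes$target)
  ls <- genome_length(genomes$spikein)
  p_spike <- (config$n_spikein_cells * ls) /
    (config$n_target_cells * lt + config$n_spikein_cells * ls)
  is_spike <- stats::runif(n) < p_spike
  out <- vector("list", 2)
  for (k in 1:2) {
    g <- if (k == 1) genomes$target else genomes$spikein
    idx <- if (k == 1) !is_spike else is_spike
    m <- sum(idx)
    if (m == 0) {
      out[[k]] <- empty_fragments()
      next
    }
    widths <- Biostrings::width(g$seqs)
    ci <- sample.int(length(widths), m, replace = TRUE, prob = widths)
    len <- pmax(config$read_length,
                as.integer(round(stats::rnorm(m, config$fragment_length_mean,
                                              config$fragment_length_sd))))
    len <- pmin(len, widths[ci])
    start <- as.integer(floor(stats::runif(m) * (widths[ci] - len + 1)))
    chrom <- names(g$seqs)[ci]
    marked <- fragments_overlap_loci(chrom, start, len, g$marked_loci)
    out[[k]] <- data.frame(genome = g$label, chrom = chrom, start = start,
                           fraglen = len, marked = marked,
                           stringsAsFactors = FALSE)
  }
  frags <- rbind(out[[1]], out[[2]])
  # restore pool draw order so results don't depend on genome block order
  ord <- integer(n)
  ord[!is_spike] <- seq_len(sum(!is_spike))
  ord[is_spike] <- sum(!is_spike) + seq_len(sum(is_spike))
  frags[ord, , drop = FALSE]
}

fragments_overlap_loci <- function(chrom, start, len, loci) {
  if (is.null(loci) || nrow(loci) == 0) return(rep(FALSE, length(start)))
  fr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start + 1L, start + len))
  lo <- GenomicRanges::GRanges(loci$chrom,
                               IRanges::IRanges(loci$start + 1L, loci$end))
  IRanges::overlapsAny(fr, lo)
}

# Rejection-sample pulldown fragments until `depth` are captured.
sample_pulldown_fragments <- function(depth, condition, config, genomes) {
  occ_target <- config$base_occupancy *
    if (condition == "treated") config$fold_change else 1
  occ_spike <- config$base_occupancy
  p_marked_t <- min(1, config$pulldown_efficiency * occ_target)
  p_marked_s <- min(1, config$pulldown_efficiency * occ_spike)
  p_bg <- config$background_capture
  accepted <- list()
  have <- 0L
  # conservative acceptance-rate guess for batch sizing
  rate <- max(1e-4, p_bg + 0.1 * max(p_marked_t, p_marked_s))
  while (have < depth) {
    batch <- ceiling((depth - have) / rate * 1.2) + 1000L
    batch <- min(batch, 5e6)
    cand <- draw_fragments(batch, config, genomes)
    p <- ifelse(cand$marked,
                ifelse(cand$genome == "target", p_marked_t, p_marked_s),
                p_bg)
    keep <- stats::runif(batch) < p
    got <- cand[keep, , drop = FALSE]
    if (nrow(got) > 0) {
      accepted[[length(accepted) + 1L]] <- got
      have <- have + nrow(got)
      rate <- max(rate, nrow(got) / batch)
    }
  }
  frags <- do.call(rbind, accepted)
  utils::head(frags, depth)
}

# Sequence the captured fragments: uniform strand choice, read = first
# read_length bases from the fragment's 5' end on that strand.
fragments_to_reads <- function(frags, sample_id, config, genomes) {
  n <- nrow(frags)
  L <- config$read_length
  cols <- c("id", "sequence", "truth_genome", "truth_chrom", "truth_start",
            "truth_strand")
  if (config$paired) cols <- append(cols, "mate", after = 2)
  if (n == 0) {
    df <- stats::setNames(rep(list(character()), length(cols)), cols)
    df$truth_start <- integer()
    return(as.data.frame(df, stringsAsFactors = FALSE))
  }
  strand <- ifelse(stats::runif(n) < 0.5, "+", "-")
  read_start <- ifelse(strand == "+", frags$start,
                       frags$start + frags$fraglen - L)
  seqcache <- c(as.list(as.character(genomes$target$seqs)),
                as.list(as.character(genomes$spikein$seqs)))
  extract <- function(starts) {
    out <- character(n)
    for (ch in unique(frags$chrom)) {
      idx <- which(frags$chrom == ch)
      out[idx] <- substring(seqcache[[ch]], starts[idx] + 1L, starts[idx] + L)
    }
    out
  }
  fwd_read <- extract(read_start)
  seq <- fwd_read
  neg <- strand == "-"
  if (any(neg)) seq[neg] <- revcomp(fwd_read[neg])
  df <- data.frame(
    id = sprintf("%s_%07d", sample_id, seq_len(n)),
    sequence = seq,
    truth_genome = frags$genome,
    truth_chrom = frags$chrom,
    truth_start = as.integer(read_start),
    truth_strand = strand,
    stringsAsFactors = FALSE
  )
  if (config$paired) {
    mate_start <- ifelse(strand == "+", frags$start + frags$fraglen - L,
                         frags$start)
    mate_fwd <- extract(mate_start)
    pos <- !neg
    if (any(pos)) mate_fwd[pos] <- revcomp(mate_fwd[pos])
    df$mate <- mate_fwd
    df <- df[, c("id", "sequence", "mate", "truth_genome", "truth_chrom",
                 "truth_start", "truth_strand")]
  }
  df
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Write a library's reads as FASTQ
#'
#' Single-end libraries yield one file; paired libraries yield `_R1`/`_R2`
#' files. Qualities are constant (synthetic reads carry no error model).
#'
#' @param library A `SampleLibrary`.
#' @param path Output path (for paired data, used as a stem).
#' @return Character vector of the file(s) written, invisibly.
#' @export
write_fastq <- function(library, path) {
  reads <- library$reads
  paired <- "mate" %in% names(reads)
  emit <- function(ids, seqs, file) {
    qual <- vapply(nchar(seqs), function(w) strrep("I", w), "")
    writeLines(as.vector(rbind(paste0("@", ids), seqs, "+", qual)), file)
    file
  }
  if (!paired) {
    return(invisible(emit(reads$id, reads$sequence, path)))
  }
  stem <- sub("\\.fastq$|\\.fq$", "", path)
  f1 <- emit(paste0(reads$id, "/1"), reads$sequence,
             paste0(stem, "_R1.fastq"))
  f2 <- emit(paste0(reads$id, "/2"), reads$mate, paste0(stem, "_R2.fastq"))
  invisible(c(f1, f2))
}

#' Read a FASTQ file into a bare read table
#'
#' Import path for externally produced reads; no truth tags are attached.
#'
#' @param path FASTQ path.
#' @return A data.frame with columns `id` and `sequence`.
#' @export
read_fastq <- function(path) {
  s <- Biostrings::readDNAStringSet(path, format = "fastq")
  data.frame(id = sub("\\s.*$", "", names(s)), sequence = as.character(s),
             stringsAsFactors = FALSE)
}

#' Write the library manifest
#'
#' @param libs List of `SampleLibrary` objects.
#' @param paths Character vector of the FASTQ path written for each library.
#' @param path Output TSV path.
#' @export
write_manifest <- function(libs, paths, path) {
  df <- data.frame(
    sample_id = vapply(libs, `[[`, "", "sample_id"),
    role = vapply(libs, `[[`, "", "role"),
    condition = vapply(libs, `[[`, "", "condition"),
    fastq = paths,
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
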