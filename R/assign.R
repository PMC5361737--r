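#' Index a concatenated two-species genome
#'
#' Mirrors the concatenated-genome trick used in spike-in ChIP-seq: target
#' and spike-in chromosomes are merged into one coordinate space, with
#' chromosome names prefixed `"target|"` / `"spikein|"` so every position
#' carries unambiguous genome attribution. The index supports exact-match
#' queries over both strands of all chromosomes.
#'
#' @param target,spikein `ReferenceGenome`s with the corresponding labels.
#' @return A `GenomeIndex` object.
#' @export
index_concatenated_genome <- function(target, spikein) {
  stopifnot(inherits(target, "ReferenceGenome"),
            inherits(spikein, "ReferenceGenome"))
  if (target$label != "target" || spikein$label != "spikein") {
    stop("arguments must be the target and spikein genomes, in that order")
  }
  seqs <- c(stats::setNames(target$seqs,
                            paste0("target|", names(target$seqs))),
            stats::setNames(spikein$seqs,
                            paste0("spikein|", names(spikein$seqs))))
  if (anyDuplicated(names(seqs))) {
    stop("duplicate chromosome name across genomes after prefixing")
  }
  structure(list(
    seqs = seqs,
    labels = stats::setNames(
      rep(c("target", "spikein"),
          c(length(target$seqs), length(spikein$seqs))),
      names(seqs)),
    seqlengths = stats::setNames(Biostrings::width(seqs), names(seqs))
  ), class = "GenomeIndex")
}

#' @export
print.GenomeIndex <- function(x, ...) {
  cat(sprintf("GenomeIndex: %d chromosome(s), %d bp (%d target + %d spikein)\n",
              length(x$seqs), sum(x$seqlengths),
              sum(x$seqlengths[x$labels == "target"]),
              sum(x$seqlengths[x$labels == "spikein"])))
  invisible(x)
}

#' Find every exact occurrence of a query in the indexed genome
#'
#' Searches both strands of every chromosome. A minus-strand occurrence is
#' reported at the forward-strand interval its reverse complement occupies.
#'
#' @param index A `GenomeIndex`.
#' @param query A nucleotide string.
#' @return data.frame with columns `chrom` (prefixed), `start` (0-based),
#'   `end` (exclusive), `strand`, `genome`.
#' @export
find_occurrences <- function(index, query) {
  q <- Biostrings::DNAString(query)
  rq <- Biostrings::reverseComplement(q)
  hits <- list()
  for (ch in names(index$seqs)) {
    subj <- index$seqs[[ch]]
    for (st in c("+", "-")) {
      m <- Biostrings::matchPattern(if (st == "+") q else rq, subj)
      if (length(m)) {
        hits[[length(hits) + 1L]] <- data.frame(
          chrom = ch, start = BiocGenerics::start(m) - 1L,
          end = BiocGenerics::end(m), strand = st,
          genome = unname(index$labels[ch]), stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      genome = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, hits)
}

#' Per-library read-assignment tallies
#'
#' The four buckets partition the input exactly: every read is either
#' uniquely assigned to the target genome, uniquely assigned to the
#' spike-in genome, discarded for mapping to two or more locations, or
#' unmapped.
#'
#' @param n_target,n_spikein,n_discarded_multi,n_unmapped Counts.
#' @return A `CountSummary`.
#' @export
count_summary <- function(n_target, n_spikein, n_discarded_multi = 0,
                          n_unmapped = 0) {
  x <- list(n_target = as.numeric(n_target),
            n_spikein = as.numeric(n_spikein),
            n_discarded_multi = as.numeric(n_discarded_multi),
            n_unmapped = as.numeric(n_unmapped))
  if (any(unlist(x) < 0)) stop("CountSummary fields must be >= 0")
  structure(x, class = "CountSummary")
}

#' @export
print.CountSummary <- function(x, ...) {
  cat(sprintf(
    "CountSummary: %g target, %g spikein, %g multi-discarded, %g unmapped\n",
    x$n_target, x$n_spikein, x$n_discarded_multi, x$n_unmapped))
  invisible(x)
}

total_aligned <- function(counts) counts$n_target + counts$n_spikein

#' Assign reads to the concatenated genome, keeping unique mappers only
#'
#' Each read is searched for exact matches over both strands of both
#' genomes. A read with exactly one occurrence yields one alignment; zero
#' occurrences means unmapped; two or more means discarded (the
#' unique-mapping rule that makes per-genome read counting meaningful).
#' Exact matching with zero mismatches stands in for a short-read aligner
#' restricted to uniquely mapping reads, which is faithful for synthetic
#' error-free reads; externally produced alignments can instead be imported
#' with [read_alignments_bed()].
#'
#' @param reads A `SampleLibrary` or a data.frame with columns `id` and
#'   `sequence`. All reads must share one length.
#' @param index A `GenomeIndex`.
#' @return list with `alignments` (a [GenomicRanges::GRanges] in the
#'   prefixed coordinate space, with `read_id` and `genome` metadata
#'   columns) and `counts` (a `CountSummary` partitioning the input).
#' @export
assign_reads <- function(reads, index) {
  if (inherits(reads, "SampleLibrary")) reads <- reads$reads
  n <- nrow(reads)
  if (n == 0) {
    return(list(alignments = empty_alignments(index),
                counts = count_summary(0, 0, 0, 0)))
  }
  w <- nchar(reads$sequence)
  if (length(unique(w)) != 1) {
    bad <- reads$id[which(w != w[1])[1]]
    stop(sprintf("read length mismatch: read '%s' has length %d, expected %d",
                 bad, nchar(reads$sequence[reads$id == bad][1]), w[1]))
  }
  fwd <- Biostrings::DNAStringSet(reads$sequence)
  rev <- Biostrings::reverseComplement(fwd)
  pd_fwd <- Biostrings::PDict(fwd)
  pd_rev <- Biostrings::PDict(rev)
  hit_read <- list(); hit_chrom <- list(); hit_start <- list()
  hit_strand <- list()
  k <- 0L
  for (ch in names(index$seqs)) {
    subj <- index$seqs[[ch]]
    for (st in c("+", "-")) {
      m <- Biostrings::matchPDict(if (st == "+") pd_fwd else pd_rev, subj)
      cnt <- S4Vectors::elementNROWS(m)
      if (sum(cnt) == 0) next
      k <- k + 1L
      hit_read[[k]] <- rep.int(seq_len(n), cnt)
      hit_start[[k]] <- unlist(Biostrings::startIndex(m), use.names = FALSE)
      hit_chrom[[k]] <- rep.int(ch, sum(cnt))
      hit_strand[[k]] <- rep.int(st, sum(cnt))
    }
  }
  ridx <- unlist(hit_read, use.names = FALSE)
  occ <- tabulate(ridx, nbins = n)
  uniq <- occ == 1L
  keep <- uniq[ridx]
  ord <- order(ridx[keep])
  chrom <- unlist(hit_chrom, use.names = FALSE)[keep][ord]
  start1 <- unlist(hit_start, use.names = FALSE)[keep][ord]
  strand <- unlist(hit_strand, use.names = FALSE)[keep][ord]
  rid <- reads$id[ridx[keep][ord]]
  genome <- unname(index$labels[chrom])
  gr <- GenomicRanges::GRanges(
    seqnames = factor(chrom, levels = names(index$seqs)),
    ranges = IRanges::IRanges(start1, width = w[1]),
    strand = strand,
    read_id = rid, genome = genome,
    seqlengths = index$seqlengths)
  counts <- count_summary(
    n_target = sum(genome == "target"),
    n_spikein = sum(genome == "spikein"),
    n_discarded_multi = sum(occ >= 2L),
    n_unmapped = sum(occ == 0L))
  stopifnot(total_aligned(counts) + counts$n_discarded_multi +
              counts$n_unmapped == n)
  list(alignments = gr, counts = counts)
}

empty_alignments <- function(index) {
  GenomicRanges::GRanges(
    seqnames = factor(character(), levels = names(index$seqs)),
    ranges = IRanges::IRanges(), strand = character(),
    read_id = character(), genome = character(),
    seqlengths = index$seqlengths)
}

#' Write / read alignments as BED6
#'
#' BED columns: prefixed chromosome, 0-based start, end, read id, score 0,
#' strand. On import the genome label is inferred from the `"target|"` /
#' `"spikein|"` chromosome-name prefix, so externally produced alignments
#' against the concatenated genome can be slotted into the pipeline.
#'
#' @param alignments GRanges as returned by [assign_reads()].
#' @param path BED path.
#' @export
write_alignments_bed <- function(alignments, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s",
                   as.character(GenomicRanges::seqnames(alignments)),
                   BiocGenerics::start(alignments) - 1L,
                   BiocGenerics::end(alignments),
                   alignments$read_id,
                   as.character(BiocGenerics::strand(alignments)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_alignments_bed
#' @param seqlengths Optional named vector of chromosome lengths to attach.
#' @export
read_alignments_bed <- function(path, seqlengths = NULL) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "name",
                                        "score", "strand"),
                          colClasses = c("character", "integer", "integer",
                                         "character", "numeric", "character"))
  genome <- sub("\\|.*$", "", df$chrom)
  if (!all(genome %in% c("target", "spikein"))) {
    stop("chromosome names must carry a 'target|' or 'spikein|' prefix")
  }
  if (is.null(seqlengths)) {
    GenomicRanges::GRanges(df$chrom,
                           IRanges::IRanges(df$start + 1L, df$end),
                           strand = df$strand,
                           read_id = df$name, genome = genome)
  } else {
    GenomicRanges::GRanges(factor(df$chrom, levels = names(seqlengths)),
                           IRanges::IRanges(df$start + 1L, df$end),
                           strand = df$strand,
                           read_id = df$name, genome = genome,
                           seqlengths = seqlengths)
  }
}

#' Write / read a CountSummary as TSV
#' @param counts A `CountSummary`.
#' @param path TSV path.
#' @export
write_counts_tsv <- function(counts, path) {
  df <- data.frame(n_target = counts$n_target, n_spikein = counts$n_spikein,
                   n_discarded_multi = counts$n_discarded_multi,
                   n_unmapped = counts$n_unmapped)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE)
  count_summary(df$n_target, df$n_spikein, df$n_discarded_multi,
                df$n_unmapped)
}
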