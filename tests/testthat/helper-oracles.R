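# Independent oracles and small fixtures, deliberately kept free of the
# package's own matching/coverage code paths.

# Small, fast simulation config for unit tests.
tiny_config <- function(seed, ...) {
  defaults <- list(seed = seed, target_genome_size = 20000,
                   spikein_genome_size = 8000, n_marked_loci_target = 10,
                   n_marked_loci_spikein = 4, locus_width = 400,
                   depth = 2000)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

# Pure-R reverse complement (no Biostrings).
rc_chr <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }, "", USE.NAMES = FALSE)
}

# Brute-force scan of every position of every strand of every chromosome.
# Returns a data.frame like find_occurrences().
brute_occurrences <- function(seq_list, labels, query) {
  hits <- list()
  L <- nchar(query)
  rq <- rc_chr(query)
  for (ch in names(seq_list)) {
    s <- seq_list[[ch]]
    n <- nchar(s)
    if (n < L) next
    starts <- seq_len(n - L + 1L)
    subs <- substring(s, starts, starts + L - 1L)
    for (st in c("+", "-")) {
      q <- if (st == "+") query else rq
      at <- which(subs == q)
      if (length(at)) {
        hits[[length(hits) + 1L]] <- data.frame(
          chrom = ch, start = at - 1L, end = at - 1L + L, strand = st,
          genome = labels[[ch]], stringsAsFactors = FALSE)
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

# Brute-force read assignment: classify every read by its total occurrence
# count over both strands of both genomes.
brute_assign <- function(reads, seq_list, labels) {
  out <- lapply(seq_len(nrow(reads)), function(i) {
    occ <- brute_occurrences(seq_list, labels, reads$sequence[i])
    if (nrow(occ) == 0) {
      data.frame(id = reads$id[i], bucket = "unmapped", chrom = NA,
                 start = NA, strand = NA, stringsAsFactors = FALSE)
    } else if (nrow(occ) == 1) {
      data.frame(id = reads$id[i], bucket = occ$genome, chrom = occ$chrom,
                 start = occ$start, strand = occ$strand,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(id = reads$id[i], bucket = "multi", chrom = NA,
                 start = NA, strand = NA, stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, out)
}

# Per-base depth oracle: expand read intervals into a base vector.
brute_depth <- function(starts, ends, chrom_len) {
  depth <- numeric(chrom_len)
  for (i in seq_along(starts)) {
    idx <- (starts[i] + 1L):ends[i]
    depth[idx] <- depth[idx] + 1
  }
  depth
}

# Index helpers for handmade genomes.
make_index <- function(target_seqs, spikein_seqs) {
  index_concatenated_genome(reference_genome("target", target_seqs),
                            reference_genome("spikein", spikein_seqs))
}

# Random DNA string (test-local randomness, caller controls the seed).
rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# GRanges of single-end alignments over one target chromosome.
make_aln <- function(starts0, width, chrom = "target|chr1",
                     chrom_len = 10000, strand = "+") {
  GenomicRanges::GRanges(
    seqnames = factor(rep(chrom, length(starts0)), levels = chrom),
    ranges = IRanges::IRanges(starts0 + 1L, width = width),
    strand = rep_len(strand, length(starts0)),
    read_id = sprintf("r%d", seq_along(starts0)),
    genome = rep("target", length(starts0)),
    seqlengths = stats::setNames(chrom_len, chrom))
}

# Does a read's alignment agree with its simulation truth tag?
truth_matches <- function(alignments, reads) {
  key <- match(alignments$read_id, reads$id)
  chrom_ok <- as.character(GenomicRanges::seqnames(alignments)) ==
    paste0(reads$truth_genome[key], "|", reads$truth_chrom[key])
  pos_ok <- BiocGenerics::start(alignments) - 1L == reads$truth_start[key]
  chrom_ok & pos_ok
}
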