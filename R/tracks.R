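#' Scaled coverage track
#'
#' A run-length encoded, strand-resolved coverage track: non-overlapping
#' sorted intervals (0-based half-open, bedGraph convention) each carrying
#' one constant value. Zero-coverage runs are omitted. Construction
#' enforces the mass-conservation invariant: the sum of `value * length`
#' over all intervals equals `scale` times the total aligned bases of the
#' selected strand(s), to within 1e-9 relative tolerance.
#'
#' @param intervals data.frame with columns `chrom`, `start`, `end`,
#'   `value`.
#' @param sample_id Sample identifier.
#' @param strand `"+"`, `"-"` or `"both"`.
#' @param normalization `"rpm"`, `"spikein"` or `"raw"`.
#' @param scale The multiplicative factor applied to raw per-base depth.
#' @param aligned_bases Total aligned bases underlying the track.
#' @param seqlengths Named vector of chromosome lengths.
#' @return A `CoverageTrack`.
#' @export
coverage_track <- function(intervals, sample_id, strand, normalization,
                           scale, aligned_bases, seqlengths) {
  strand <- match.arg(strand, c("+", "-", "both"))
  normalization <- match.arg(normalization, c("rpm", "spikein", "raw"))
  stopifnot(all(c("chrom", "start", "end", "value") %in% names(intervals)))
  if (nrow(intervals)) {
    stopifnot(all(intervals$end > intervals$start),
              all(intervals$value >= 0),
              all(intervals$chrom %in% names(seqlengths)),
              all(intervals$start >= 0),
              all(intervals$end <= seqlengths[intervals$chrom]))
    ord <- order(match(intervals$chrom, names(seqlengths)), intervals$start)
    intervals <- intervals[ord, , drop = FALSE]
    rownames(intervals) <- NULL
    by_chrom <- split(intervals, intervals$chrom)
    for (b in by_chrom) {
      if (nrow(b) > 1 && any(b$start[-1] < b$end[-nrow(b)])) {
        stop("track intervals overlap")
      }
    }
  }
  mass <- sum(intervals$value * (intervals$end - intervals$start))
  expected <- scale * aligned_bases
  if (expected > 0 &&
      abs(mass - expected) > 1e-9 * max(abs(mass), abs(expected))) {
    stop(sprintf("track mass %.12g != scale x aligned bases %.12g",
                 mass, expected))
  }
  structure(list(intervals = intervals, sample_id = sample_id,
                 strand = strand, normalization = normalization,
                 scale = scale, aligned_bases = aligned_bases,
                 seqlengths = seqlengths),
            class = "CoverageTrack")
}

#' @export
print.CoverageTrack <- function(x, ...) {
  cat(sprintf(
    "CoverageTrack %s [strand %s, %s-normalized]: %d intervals, mass %.6g\n",
    x$sample_id, x$strand, x$normalization, nrow(x$intervals),
    track_mass(x)))
  invisible(x)
}

track_mass <- function(track) {
  sum(track$intervals$value * (track$intervals$end - track$intervals$start))
}

#' Build a scaled bedGraph-style coverage track from alignments
#'
#' Per-base depth of the aligned read intervals, multiplied by `scale` and
#' run-length encoded. Reads are counted over their full aligned interval;
#' an optional 3' extension to the expected fragment length is available
#' via `extend` (default 0, i.e. no fragment extension).
#'
#' @param alignments GRanges of aligned reads (with seqlengths set).
#' @param scale Multiplicative normalization factor (> 0); use a
#'   `ScalingResult`'s `scale_factor` for spike-in normalization or its
#'   `rpm_factor` for RPM.
#' @param strand_mode `"+"`, `"-"` or `"both"`.
#' @param sample_id,normalization Labels carried on the track.
#' @param extend Extend each read to this fragment length in its 3'
#'   direction (0 = no extension). Extensions are clipped at chromosome
#'   ends.
#' @return A `CoverageTrack`.
#' @export
coverage_bedgraph <- function(alignments, scale, strand_mode = "both",
                              sample_id = "sample", normalization = "raw",
                              extend = 0) {
  strand_mode <- match.arg(strand_mode, c("+", "-", "both"))
  stopifnot(scale > 0)
  sl <- GenomeInfoDb::seqlengths(alignments)
  if (anyNA(sl)) stop("alignments must carry chromosome lengths")
  if (length(alignments)) {
    ends <- BiocGenerics::end(alignments)
    lim <- sl[as.character(GenomicRanges::seqnames(alignments))]
    if (any(BiocGenerics::start(alignments) < 1) || any(ends > lim)) {
      stop("alignment outside chromosome bounds")
    }
  }
  gr <- alignments
  if (strand_mode != "both") {
    gr <- gr[as.character(BiocGenerics::strand(gr)) == strand_mode]
  }
  if (extend > 0) {
    gr <- GenomicRanges::resize(gr, pmax(GenomicRanges::width(gr), extend))
    gr <- GenomicRanges::trim(gr)
  }
  cov <- GenomicRanges::coverage(gr)
  rows <- lapply(names(cov), function(ch) {
    r <- cov[[ch]]
    rl <- S4Vectors::runLength(r)
    rv <- S4Vectors::runValue(r)
    ends <- cumsum(rl)
    keep <- rv > 0
    if (!any(keep)) return(NULL)
    data.frame(chrom = ch, start = (ends - rl)[keep], end = ends[keep],
               value = rv[keep] * scale, stringsAsFactors = FALSE)
  })
  intervals <- do.call(rbind, rows)
  if (is.null(intervals)) {
    intervals <- data.frame(chrom = character(), start = integer(),
                            end = integer(), value = numeric())
  }
  coverage_track(intervals, sample_id = sample_id, strand = strand_mode,
                 normalization = normalization, scale = scale,
                 aligned_bases = sum(GenomicRanges::width(gr)),
                 seqlengths = sl)
}

# Per-chromosome numeric Rle over the full chromosome, for window lookups.
track_rlelist <- function(track) {
  sl <- track$seqlengths
  out <- lapply(names(sl), function(ch) {
    b <- track$intervals[track$intervals$chrom == ch, , drop = FALSE]
    r <- S4Vectors::Rle(0, sl[[ch]])
    if (nrow(b)) {
      r[IRanges::IRanges(b$start + 1L, b$end)] <-
        S4Vectors::Rle(b$value, b$end - b$start)
    }
    r
  })
  stats::setNames(out, names(sl))
}

#' Average coverage profile around transcription start sites
#'
#' Extracts the coverage vector over `[pos - window, pos + window)` for
#' every TSS, flips it for minus-strand sites so that downstream of the
#' TSS always points right, averages per-base across sites, and bins the
#' averaged profile by mean into `bin`-bp bins. Sites whose window exceeds
#' the chromosome are skipped and counted in `n_skipped`.
#'
#' @param track A `CoverageTrack`.
#' @param tss data.frame with columns `chrom`, `pos` (0-based TSS
#'   coordinate) and `strand`.
#' @param window Half-window in bp (profile spans `-window` to `+window`).
#' @param bin Bin width in bp; `window` must be a multiple of `bin`.
#' @return A `MetageneProfile`: list with `offsets` (bin centers relative
#'   to the TSS), `values` (mean coverage per bin), `n_sites`,
#'   `n_skipped`, plus the track's normalization label.
#' @export
metagene_tss <- function(track, tss, window = 2000, bin = 25) {
  stopifnot(inherits(track, "CoverageTrack"))
  if (nrow(tss) == 0) stop("tss list must be non-empty")
  if (window %% bin != 0) stop("window must be a multiple of bin")
  rl <- track_rlelist(track)
  width <- 2L * window
  acc <- numeric(width)
  n_sites <- 0L
  n_skipped <- 0L
  for (i in seq_len(nrow(tss))) {
    ch <- tss$chrom[i]
    lo <- tss$pos[i] - window      # 0-based inclusive
    hi <- tss$pos[i] + window      # 0-based exclusive
    if (!ch %in% names(rl) || lo < 0 || hi > length(rl[[ch]])) {
      n_skipped <- n_skipped + 1L
      next
    }
    v <- as.numeric(S4Vectors::window(rl[[ch]], lo + 1L, hi))
    if (identical(tss$strand[i], "-")) v <- rev(v)
    acc <- acc + v
    n_sites <- n_sites + 1L
  }
  if (n_sites == 0) stop("all TSS windows fell outside chromosome bounds")
  mean_profile <- acc / n_sites
  nb <- width %/% bin
  values <- colMeans(matrix(mean_profile, nrow = bin, ncol = nb))
  offsets <- seq(-window, window - bin, by = bin) + bin / 2
  structure(list(offsets = offsets, values = values, n_sites = n_sites,
                 n_skipped = n_skipped,
                 normalization = track$normalization),
            class = "MetageneProfile")
}

#' @export
print.MetageneProfile <- function(x, ...) {
  cat(sprintf(
    "MetageneProfile (%s): %d bins over [%g, %g], %d sites (%d skipped)\n",
    x$normalization, length(x$values), min(x$offsets), max(x$offsets),
    x$n_sites, x$n_skipped))
  invisible(x)
}

#' Mean scaled coverage within peaks
#'
#' Per-peak mean per-base value (zeros included), and the overall mean
#' across peaks. The overall mean is unweighted by peak length: each peak
#' contributes equally regardless of its width.
#'
#' @param track A `CoverageTrack`.
#' @param peaks data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open).
#' @return list with `per_peak` (the peaks table plus a `mean_coverage`
#'   column) and `overall_mean`.
#' @export
peak_mean_coverage <- function(track, peaks) {
  stopifnot(inherits(track, "CoverageTrack"))
  if (is.null(peaks) || nrow(peaks) == 0) stop("empty peak list")
  rl <- track_rlelist(track)
  means <- vapply(seq_len(nrow(peaks)), function(i) {
    ch <- peaks$chrom[i]
    if (!ch %in% names(rl)) return(0)
    lo <- max(0L, peaks$start[i])
    hi <- min(length(rl[[ch]]), peaks$end[i])
    if (hi <= lo) return(0)
    mean(as.numeric(S4Vectors::window(rl[[ch]], lo + 1L, hi)))
  }, numeric(1))
  per_peak <- cbind(peaks, mean_coverage = means)
  list(per_peak = per_peak, overall_mean = mean(means))
}

#' Write / read a track as a 4-column bedGraph file
#'
#' Values are written with 17 significant digits so that a write/read
#' round trip reproduces them exactly.
#'
#' @param track A `CoverageTrack`.
#' @param path bedGraph path.
#' @param header Include a `track type=bedGraph` header line.
#' @export
write_bedgraph <- function(track, path, header = FALSE) {
  con <- file(path, "w")
  on.exit(close(con))
  if (header) {
    writeLines(sprintf('track type=bedGraph name="%s_%s_%s"',
                       track$sample_id, track$strand, track$normalization),
               con)
  }
  b <- track$intervals
  writeLines(sprintf("%s\t%d\t%d\t%.17g", b$chrom, b$start, b$end, b$value),
             con)
  invisible(path)
}

#' @rdname write_bedgraph
#' @param sample_id,strand,normalization,scale,aligned_bases,seqlengths
#'   Track metadata to attach on read (bedGraph itself stores only the
#'   intervals).
#' @export
read_bedgraph <- function(path, sample_id, strand, normalization, scale,
                          aligned_bases, seqlengths) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "track")]
  if (!length(lines)) {
    intervals <- data.frame(chrom = character(), start = integer(),
                            end = integer(), value = numeric())
  } else {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    intervals <- data.frame(
      chrom = vapply(parts, `[`, "", 1),
      start = as.integer(vapply(parts, `[`, "", 2)),
      end = as.integer(vapply(parts, `[`, "", 3)),
      value = as.numeric(vapply(parts, `[`, "", 4)),
      stringsAsFactors = FALSE)
  }
  coverage_track(intervals, sample_id = sample_id, strand = strand,
                 normalization = normalization, scale = scale,
                 aligned_bases = aligned_bases, seqlengths = seqlengths)
}

#' Write a metagene profile as TSV
#' @param profile A `MetageneProfile`.
#' @param path TSV path.
#' @export
write_metagene_tsv <- function(profile, path) {
  df <- data.frame(offset = profile$offsets, value = profile$values,
                   normalization = profile$normalization,
                   n_sites = profile$n_sites)
  write_numeric_tsv(df, path)
  invisible(path)
}
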