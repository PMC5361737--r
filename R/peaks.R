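#' Call broad peaks with a sliding-window Poisson test
#'
#' A self-contained stand-in for an external broad-peak caller. The target
#' genome is tiled with `window`-bp windows every `step` bp; in each
#' window the pulldown read count is tested against a Poisson background
#' whose rate is the depth-matched input count,
#' `lambda = input_count * depth_ratio`, floored at the genome-average
#' pulldown pseudorate (`total_pulldown_reads * window / genome_length`)
#' so that windows with zero input coverage are not trivially significant.
#' Windows with `p < alpha` and at least `min_reads` pulldown reads are
#' kept; surviving windows are merged when they overlap, abut, or lie
#' within `merge_gap` bp of each other. P-values are not
#' multiplicity-corrected; `alpha` is strict instead.
#'
#' Spike-in reads are excluded: peaks are features of the target genome,
#' and depth matching uses uniquely aligned target-genome reads only.
#' Reads are assigned to windows by midpoint so each read counts once.
#'
#' @param pulldown_alignments,input_alignments GRanges of aligned reads
#'   (with `genome` metadata column and seqlengths).
#' @param window,step Window width and stride in bp.
#' @param alpha Per-window Poisson significance threshold.
#' @param merge_gap Merge significant windows within this many bp.
#' @param min_reads Minimum pulldown reads per significant window.
#' @return data.frame of peaks: `chrom`, `start`, `end` (0-based
#'   half-open), `name`, `score` (-log10 p of the merged-peak test),
#'   `strand` (`.`), `fold_enrichment`, `neg_log10_p`.
#' @export
call_broad_peaks <- function(pulldown_alignments, input_alignments,
                             window = 200, step = 100, alpha = 1e-5,
                             merge_gap = 1000, min_reads = 5) {
  stopifnot(window > 0, step > 0, alpha > 0, merge_gap >= 0, min_reads > 0)
  pd <- target_only(pulldown_alignments)
  ip <- target_only(input_alignments)
  if (length(ip) == 0) stop("empty input library: no background model")
  if (length(pd) == 0) stop("empty pulldown library")
  sl <- GenomeInfoDb::seqlengths(pd)
  sl <- sl[grepl("^target\\|", names(sl))]
  genome_len <- sum(sl)
  depth_ratio <- length(pd) / length(ip)
  pseudorate <- length(pd) * window / genome_len
  pd_mid <- midpoints(pd)
  ip_mid <- midpoints(ip)
  peak_rows <- list()
  for (ch in names(sl)) {
    L <- sl[[ch]]
    starts <- seq(0L, max(0L, L - window), by = step)
    win <- GenomicRanges::GRanges(ch, IRanges::IRanges(starts + 1L,
                                                       pmin(starts + window, L)))
    cnt_pd <- GenomicRanges::countOverlaps(win, pd_mid)
    cnt_ip <- GenomicRanges::countOverlaps(win, ip_mid)
    lambda <- pmax(cnt_ip * depth_ratio, pseudorate)
    p <- stats::ppois(cnt_pd - 1, lambda, lower.tail = FALSE)
    keep <- p < alpha & cnt_pd >= min_reads
    if (!any(keep)) next
    merged <- GenomicRanges::reduce(win[keep], min.gapwidth = merge_gap + 1L)
    for (j in seq_along(merged)) {
      m <- merged[j]
      n_pd <- GenomicRanges::countOverlaps(m, pd_mid)
      n_ip <- GenomicRanges::countOverlaps(m, ip_mid)
      w <- GenomicRanges::width(m)
      lam <- max(n_ip * depth_ratio, length(pd) * w / genome_len)
      peak_rows[[length(peak_rows) + 1L]] <- data.frame(
        chrom = ch,
        start = BiocGenerics::start(m) - 1L,
        end = BiocGenerics::end(m),
        fold_enrichment = n_pd / lam,
        neg_log10_p = -stats::ppois(n_pd - 1, lam, lower.tail = FALSE,
                                    log.p = TRUE) / log(10),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(peak_rows)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character(),
                      score = numeric(), strand = character(),
                      fold_enrichment = numeric(),
                      neg_log10_p = numeric(), stringsAsFactors = FALSE))
  }
  peaks <- do.call(rbind, peak_rows)
  peaks$name <- sprintf("peak_%d", seq_len(nrow(peaks)))
  peaks$score <- peaks$neg_log10_p
  peaks$strand <- "."
  peaks[, c("chrom", "start", "end", "name", "score", "strand",
            "fold_enrichment", "neg_log10_p")]
}

target_only <- function(gr) {
  if (!is.null(gr$genome)) gr[gr$genome == "target"] else gr
}

midpoints <- function(gr) {
  mid <- (BiocGenerics::start(gr) + BiocGenerics::end(gr)) %/% 2L
  GenomicRanges::GRanges(GenomicRanges::seqnames(gr),
                         IRanges::IRanges(mid, width = 1L))
}

#' Write / read broadPeak-like BED6+ peak files
#'
#' Columns: chrom, start, end, name, score (-log10 p), strand (`.`),
#' fold_enrichment, -log10 p. `read_broadpeak` also accepts externally
#' produced broadPeak files (ENCODE BED6+3: signalValue, pValue, qValue),
#' mapping signalValue to fold_enrichment, so real peak-caller output can
#' be substituted.
#'
#' @param peaks data.frame from [call_broad_peaks()].
#' @param path Output path.
#' @export
write_broadpeak <- function(peaks, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t%.17g\t%s\t%.17g\t%.17g",
                   peaks$chrom, peaks$start, peaks$end, peaks$name,
                   peaks$score, peaks$strand, peaks$fold_enrichment,
                   peaks$neg_log10_p)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_broadpeak
#' @export
read_broadpeak <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character(),
                      score = numeric(), strand = character(),
                      fold_enrichment = numeric(), neg_log10_p = numeric(),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 7)) stop("broadPeak file needs at least 7 columns")
  get <- function(i) vapply(parts, `[`, "", i)
  df <- data.frame(chrom = get(1), start = as.integer(get(2)),
                   end = as.integer(get(3)), name = get(4),
                   score = as.numeric(get(5)), strand = get(6),
                   fold_enrichment = as.numeric(get(7)),
                   stringsAsFactors = FALSE)
  df$neg_log10_p <- if (all(nf >= 8)) as.numeric(get(8)) else df$score
  df
}
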