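#' Spike-in reads per million aligned reads
#'
#' The fraction of uniquely aligned reads that fall on the spike-in genome,
#' expressed per million total aligned reads:
#' `1e6 * n_spikein / (n_target + n_spikein)`.
#'
#' @param counts A `CountSummary`.
#' @return Spike-in RPM (numeric scalar).
#' @export
#' @examples
#' sf9_rpm(count_summary(n_target = 8e6, n_spikein = 2e6))  # 200000
sf9_rpm <- function(counts) {
  tot <- total_aligned(counts)
  if (tot <= 0) stop("zero aligned reads: cannot compute spike-in RPM")
  1e6 * counts$n_spikein / tot
}

#' Spike-in read fraction of an input library
#'
#' `n_spikein / (n_target + n_spikein)` for the matched whole-chromatin
#' input. This fraction measures how much spike-in chromatin the sample
#' actually received, and is used to correct the pulldown's spike-in RPM
#' for pipetting variability.
#'
#' @param input_counts `CountSummary` of the matched input library.
#' @return Fraction in (0, 1].
#' @export
input_sf9_fraction <- function(input_counts) {
  tot <- total_aligned(input_counts)
  if (tot <= 0) stop("zero aligned reads in input library")
  f <- input_counts$n_spikein / tot
  if (f == 0) {
    stop("spike-in absent from input library: correction undefined")
  }
  f
}

#' Spike-in scaling factor for one pulldown
#'
#' The central ChIP-Rx quantity. The pulldown's spike-in RPM is divided by
#' the matched input's spike-in fraction (the input correction), and the
#' scaling factor is the reciprocal of that corrected value:
#'
#' \deqn{corrected = \frac{sf9\_rpm(pulldown)}{input\_sf9\_fraction(input)},
#'       \qquad scale = 1 / corrected}
#'
#' Multiplying a sample's coverage by its scale factor places all samples
#' on a common absolute scale set by the spike-in chromatin, because equal
#' amounts of spike-in material were added per cell regardless of
#' treatment. The companion `rpm_factor` (`1e6 / total aligned reads`) is
#' the conventional depth-relative normalizer used for comparison.
#'
#' Dividing by the per-sample input fraction (rather than, say, a
#' cross-sample reference fraction) cancels sample-to-sample spike-in
#' pipetting variability; any alternative correction differing by a
#' constant across samples leaves every between-sample comparison
#' unchanged.
#'
#' Because `scale_factor` is the reciprocal of a read *fraction* (per
#' million), it is itself depth-invariant, and cross-sample comparisons
#' apply it on top of the per-million step: the multiplier put on raw
#' coverage is `scale_factor * rpm_factor = input_sf9_fraction /
#' n_spikein_reads`, which depends on library composition only. For
#' equal-depth libraries this differs from applying `scale_factor` alone
#' by a constant and leaves every between-sample ratio unchanged.
#'
#' @param pulldown `CountSummary` of the pulldown library.
#' @param matched_input `CountSummary` of the same condition's input.
#' @param sample_id Identifier carried into the result.
#' @return A `ScalingResult` with fields `sample_id`, `sf9_rpm_pulldown`,
#'   `input_sf9_fraction`, `corrected_sf9_rpm`, `scale_factor`,
#'   `rpm_factor`.
#' @export
#' @examples
#' sr <- scaling_factor(count_summary(8e6, 2e6), count_summary(7.5e6, 2.5e6),
#'                      "example")
#' sr$scale_factor  # 1.25e-06
scaling_factor <- function(pulldown, matched_input, sample_id = "sample") {
  rpm <- sf9_rpm(pulldown)
  frac <- input_sf9_fraction(matched_input)
  corrected <- rpm / frac
  if (corrected == 0) {
    stop("corrected spike-in RPM is zero: no spike-in reads in pulldown")
  }
  structure(list(
    sample_id = sample_id,
    sf9_rpm_pulldown = rpm,
    input_sf9_fraction = frac,
    corrected_sf9_rpm = corrected,
    scale_factor = 1 / corrected,
    rpm_factor = 1e6 / total_aligned(pulldown)
  ), class = "ScalingResult")
}

#' @export
print.ScalingResult <- function(x, ...) {
  cat(sprintf("ScalingResult %s\n", x$sample_id))
  cat(sprintf("  pulldown spike-in RPM : %.4g\n", x$sf9_rpm_pulldown))
  cat(sprintf("  input spike-in %%     : %.4g%%\n",
              100 * x$input_sf9_fraction))
  cat(sprintf("  corrected RPM         : %.4g\n", x$corrected_sf9_rpm))
  cat(sprintf("  scale factor          : %.6g\n", x$scale_factor))
  cat(sprintf("  rpm factor            : %.6g\n", x$rpm_factor))
  invisible(x)
}

#' Write / read a table of ScalingResults as TSV
#'
#' Fractions are stored as fractions in `[0,1]`; rendering as percentages
#' is left to reports.
#'
#' @param results A list of `ScalingResult`s (or a single one).
#' @param path TSV path.
#' @export
write_scaling_tsv <- function(results, path) {
  if (inherits(results, "ScalingResult")) results <- list(results)
  df <- do.call(rbind, lapply(results, function(r) {
    data.frame(sample_id = r$sample_id,
               sf9_rpm_pulldown = r$sf9_rpm_pulldown,
               input_sf9_fraction = r$input_sf9_fraction,
               corrected_sf9_rpm = r$corrected_sf9_rpm,
               scale_factor = r$scale_factor,
               rpm_factor = r$rpm_factor)
  }))
  write_numeric_tsv(df, path)
  invisible(path)
}

#' @rdname write_scaling_tsv
#' @export
read_scaling_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(df)), function(i) {
    structure(as.list(df[i, ]), class = "ScalingResult")
  })
  stats::setNames(res, df$sample_id)
}

# TSV writer with full-precision numeric round trip.
write_numeric_tsv <- function(df, path) {
  fmt <- df
  for (j in seq_along(fmt)) {
    if (is.numeric(fmt[[j]])) fmt[[j]] <- sprintf("%.17g", fmt[[j]])
  }
  utils::write.table(fmt, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
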