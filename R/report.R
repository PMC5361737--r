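#' Genome-wide scaled signal of a track
#'
#' The sum of `value * length` over all intervals, i.e. the track's total
#' scaled coverage mass. By the track mass-conservation invariant this
#' equals `scale` times the total aligned bases, so for an RPM track of a
#' single-end library it is exactly `1e6 * read_length`.
#'
#' @param track A `CoverageTrack`.
#' @return Numeric scalar; 0 (with a warning) for an empty track.
#' @export
global_signal <- function(track) {
  stopifnot(inherits(track, "CoverageTrack"))
  if (nrow(track$intervals) == 0) {
    warning("empty track: global signal is 0")
    return(0)
  }
  track_mass(track)
}

#' Derive strand-alternating reference points from ground-truth loci
#'
#' Synthetic stand-in for a TSS annotation: the midpoint of every marked
#' locus, in the prefixed coordinate space, with alternating strands so
#' profile orientation logic is exercised.
#'
#' @param genome A `ReferenceGenome` carrying `marked_loci`.
#' @return data.frame with columns `chrom`, `pos`, `strand`.
#' @export
tss_from_loci <- function(genome) {
  loci <- genome$marked_loci
  if (is.null(loci) || nrow(loci) == 0) stop("genome carries no loci")
  data.frame(
    chrom = paste0(genome$label, "|", loci$chrom),
    pos = (loci$start + loci$end) %/% 2L,
    strand = rep_len(c("+", "-"), nrow(loci)),
    stringsAsFactors = FALSE)
}

#' Write / read a TSS annotation as BED6
#' @param tss data.frame with `chrom`, `pos`, `strand`.
#' @param path BED path.
#' @export
write_tss_bed <- function(tss, path) {
  writeLines(sprintf("%s\t%d\t%d\ttss%04d\t0\t%s", tss$chrom, tss$pos,
                     tss$pos + 1L, seq_len(nrow(tss)), tss$strand),
             path)
  invisible(path)
}

#' @rdname write_tss_bed
#' @export
read_tss_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "name",
                                        "score", "strand"),
                          colClasses = c("character", "integer", "integer",
                                         "character", "numeric", "character"))
  data.frame(chrom = df$chrom, pos = df$start, strand = df$strand,
             stringsAsFactors = FALSE)
}

# Restrict alignments to the target genome: spike-in coverage is the
# yardstick, not the measurand.
target_alignments <- function(alignments) {
  target_only(alignments)
}

#' Compare treated and vehicle conditions under both normalizations
#'
#' The head-to-head readout of spike-in quantification versus conventional
#' RPM normalization. For each replicate, coverage of the target genome is
#' built twice — once scaled by the replicate's spike-in `scale_factor`,
#' once by its depth-only `rpm_factor` — and summarized as global signal,
#' optional TSS metagene and optional peak coverage. Each replicate is
#' scaled by its own factor first; signals are then averaged across
#' replicates, and the condition ratio is the ratio of those averages.
#'
#' Under a genuine uniform global change, the spike-in ratio tracks the
#' true fold change while the RPM ratio stays near 1, because RPM
#' renormalizes away any composition-preserving change in total material.
#'
#' @param treated,vehicle Lists of replicates; each replicate is a list
#'   with elements `alignments` (GRanges from [assign_reads()]) and
#'   `scaling` (a `ScalingResult`).
#' @param tss Optional TSS annotation (`chrom`, `pos`, `strand`) for
#'   metagene tables.
#' @param peaks Optional peak table (`chrom`, `start`, `end`) for
#'   peak-coverage tables.
#' @param window,bin Metagene window and bin size (bp).
#' @return A `ComparisonReport`.
#' @export
compare_conditions <- function(treated, vehicle, tss = NULL, peaks = NULL,
                               window = 2000, bin = 25) {
  if (!length(treated) || !length(vehicle)) {
    stop("both conditions need at least one replicate")
  }
  for (side in list(treated, vehicle)) {
    for (rep in side) {
      if (is.null(rep$alignments) || is.null(rep$scaling)) {
        stop("each replicate needs 'alignments' and 'scaling' ",
             "(missing matched input pair upstream?)")
      }
    }
  }
  summarize <- function(reps, norm) {
    per_rep <- lapply(reps, function(rep) {
      # spike-in normalization is applied on top of the per-million step:
      # raw x (rpm_factor x scale_factor) = raw x input_fraction/n_spikein,
      # which depends on composition only, so sequencing depth can never
      # masquerade as a biological change
      scale <- if (norm == "spikein") {
        rep$scaling$scale_factor * rep$scaling$rpm_factor
      } else {
        rep$scaling$rpm_factor
      }
      tr <- coverage_bedgraph(target_alignments(rep$alignments), scale,
                              strand_mode = "both",
                              sample_id = rep$scaling$sample_id,
                              normalization = norm)
      list(
        global = global_signal(tr),
        metagene = if (!is.null(tss)) metagene_tss(tr, tss, window, bin),
        peak = if (!is.null(peaks)) peak_mean_coverage(tr, peaks))
    })
    glob <- mean(vapply(per_rep, `[[`, numeric(1), "global"))
    mg <- NULL
    if (!is.null(tss)) {
      mats <- lapply(per_rep, function(x) x$metagene$values)
      mg <- per_rep[[1]]$metagene
      mg$values <- Reduce(`+`, mats) / length(mats)
    }
    pk <- NULL
    if (!is.null(peaks)) {
      pk_means <- lapply(per_rep, function(x) x$peak$per_peak$mean_coverage)
      pk <- per_rep[[1]]$peak
      pk$per_peak$mean_coverage <- Reduce(`+`, pk_means) / length(pk_means)
      pk$overall_mean <- mean(pk$per_peak$mean_coverage)
    }
    list(global = glob, metagene = mg, peak = pk)
  }
  res <- list()
  for (norm in c("spikein", "rpm")) {
    res[[norm]] <- list(treated = summarize(treated, norm),
                        vehicle = summarize(vehicle, norm))
  }
  report <- list(
    global_signal = data.frame(
      condition = rep(c("treated", "vehicle"), 2),
      normalization = rep(c("spikein", "rpm"), each = 2),
      signal = c(res$spikein$treated$global, res$spikein$vehicle$global,
                 res$rpm$treated$global, res$rpm$vehicle$global)),
    spikein_ratio = res$spikein$treated$global / res$spikein$vehicle$global,
    rpm_ratio = res$rpm$treated$global / res$rpm$vehicle$global,
    metagene = if (!is.null(tss)) lapply(res, function(r) {
      list(treated = r$treated$metagene, vehicle = r$vehicle$metagene)
    }),
    peak_coverage = if (!is.null(peaks)) lapply(res, function(r) {
      list(treated = r$treated$peak, vehicle = r$vehicle$peak)
    })
  )
  if (!is.null(tss)) {
    report$tss_ratio <- vapply(report$metagene, function(m) {
      mean(m$treated$values) / mean(m$vehicle$values)
    }, numeric(1))
  }
  if (!is.null(peaks)) {
    report$peak_ratio <- vapply(report$peak_coverage, function(p) {
      p$treated$overall_mean / p$vehicle$overall_mean
    }, numeric(1))
  }
  stopifnot(report$spikein_ratio > 0, report$rpm_ratio > 0)
  class(report) <- "ComparisonReport"
  report
}

#' @export
print.ComparisonReport <- function(x, ...) {
  cat("ComparisonReport: treated / vehicle global signal ratios\n")
  cat(sprintf("  spike-in normalized : %.3f\n", x$spikein_ratio))
  cat(sprintf("  RPM normalized      : %.3f\n", x$rpm_ratio))
  if (!is.null(x$tss_ratio)) {
    cat(sprintf("  TSS coverage ratio  : %.3f (spikein) / %.3f (rpm)\n",
                x$tss_ratio[["spikein"]], x$tss_ratio[["rpm"]]))
  }
  if (!is.null(x$peak_ratio)) {
    cat(sprintf("  peak coverage ratio : %.3f (spikein) / %.3f (rpm)\n",
                x$peak_ratio[["spikein"]], x$peak_ratio[["rpm"]]))
  }
  invisible(x)
}

#' Run the whole synthetic ChIP-Rx pipeline
#'
#' simulate -> assign -> scale -> tracks -> peaks -> report, writing every
#' intermediate as a plain-text file under `outdir`. All randomness comes
#' from `config$seed`; running twice with the same config produces
#' byte-identical output files.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory (created if needed).
#' @param window,bin Metagene parameters.
#' @return The `ComparisonReport`, invisibly.
#' @export
run_chiprx <- function(config, outdir, window = 2000, bin = 25) {
  validate_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(outdir, ...)

  genomes <- build_toy_genomes(config)
  write_genome_fasta(genomes$target, p("target.fa"))
  write_genome_fasta(genomes$spikein, p("spikein.fa"))
  write_truth_bed(genomes$target, p("target_truth_loci.bed"))
  write_truth_bed(genomes$spikein, p("spikein_truth_loci.bed"))

  libs <- simulate_chiprx_experiment(config, genomes)
  fq <- vapply(libs, function(lib) {
    path <- p(paste0(lib$sample_id, ".fastq"))
    write_fastq(lib, path)
    path
  }, "")
  # manifest paths are relative to the manifest's own directory, so output
  # trees are relocatable and repeated runs are byte-identical
  write_manifest(libs, basename(fq), p("manifest.tsv"))

  index <- index_concatenated_genome(genomes$target, genomes$spikein)
  asn <- lapply(libs, function(lib) {
    a <- assign_reads(lib, index)
    write_alignments_bed(a$alignments, p(paste0(lib$sample_id, ".bed")))
    write_counts_tsv(a$counts, p(paste0(lib$sample_id, ".counts.tsv")))
    a
  })

  scalings <- list(
    treated = scaling_factor(asn$pulldown_treated$counts,
                             asn$input_treated$counts, "pulldown_treated"),
    vehicle = scaling_factor(asn$pulldown_vehicle$counts,
                             asn$input_vehicle$counts, "pulldown_vehicle"))
  write_scaling_tsv(scalings, p("scaling.tsv"))

  for (cond in c("treated", "vehicle")) {
    gr <- target_alignments(asn[[paste0("pulldown_", cond)]]$alignments)
    for (norm in c("spikein", "rpm")) {
      scale <- if (norm == "spikein") {
        scalings[[cond]]$scale_factor * scalings[[cond]]$rpm_factor
      } else {
        scalings[[cond]]$rpm_factor
      }
      for (st in c("+", "-")) {
        tr <- coverage_bedgraph(gr, scale, strand_mode = st,
                                sample_id = paste0("pulldown_", cond),
                                normalization = norm)
        tag <- if (st == "+") "plus" else "minus"
        write_bedgraph(tr, p(sprintf("pulldown_%s.%s.%s.bedgraph",
                                     cond, norm, tag)))
      }
    }
  }

  peaks <- call_broad_peaks(asn$pulldown_vehicle$alignments,
                            asn$input_vehicle$alignments)
  write_broadpeak(peaks, p("peaks.broadPeak"))

  tss <- tss_from_loci(genomes$target)
  write_tss_bed(tss, p("tss.bed"))

  report <- compare_conditions(
    treated = list(list(alignments = asn$pulldown_treated$alignments,
                        scaling = scalings$treated)),
    vehicle = list(list(alignments = asn$pulldown_vehicle$alignments,
                        scaling = scalings$vehicle)),
    tss = tss,
    peaks = if (nrow(peaks)) peaks[, c("chrom", "start", "end")],
    window = window, bin = bin)
  write_report(report, p("report.json"))
  for (norm in names(report$metagene)) {
    for (cond in c("treated", "vehicle")) {
      write_metagene_tsv(report$metagene[[norm]][[cond]],
                         p(sprintf("metagene.%s.%s.tsv", norm, cond)))
    }
  }
  if (!is.null(report$peak_coverage)) {
    for (norm in names(report$peak_coverage)) {
      for (cond in c("treated", "vehicle")) {
        write_numeric_tsv(report$peak_coverage[[norm]][[cond]]$per_peak,
                          p(sprintf("peak_coverage.%s.%s.tsv", norm, cond)))
      }
    }
  }
  invisible(report)
}

#' Write the headline comparison as JSON
#' @param report A `ComparisonReport`.
#' @param path JSON path.
#' @export
write_report <- function(report, path) {
  out <- list(
    spikein_ratio = report$spikein_ratio,
    rpm_ratio = report$rpm_ratio,
    tss_ratio = as.list(report$tss_ratio),
    peak_ratio = as.list(report$peak_ratio),
    global_signal = report$global_signal)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
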