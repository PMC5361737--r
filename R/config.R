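#' Simulation configuration for a synthetic ChIP-Rx experiment
#'
#' Collects every tunable of the synthetic-data generator in one validated
#' object. The defaults describe the experimental design being emulated:
#' 1e7 target cells mixed with 3e6 spike-in cells per sample, 83 bp
#' single-end reads, and sonicated fragments of roughly 300 bp. The toy
#' genome sizes (200 kb target, 60 kb spike-in) are free parameters chosen
#' so that ~100 marked loci fit comfortably and a full four-library
#' experiment simulates in seconds.
#'
#' @param seed Integer seed; mandatory, every random draw in the generator
#'   descends from it.
#' @param n_target_cells Number of target (e.g. human) cells per sample.
#' @param n_spikein_cells Number of spike-in (e.g. Sf9) cells per sample.
#' @param read_length Read length in bp.
#' @param paired If `TRUE`, emit both mates of each fragment. Downstream
#'   counting still treats a pair as one fragment.
#' @param fragment_length_mean,fragment_length_sd Normal fragment-length
#'   model, truncated below at `read_length`.
#' @param target_genome_size,spikein_genome_size Toy chromosome lengths (bp).
#' @param n_marked_loci_target,n_marked_loci_spikein Number of marked
#'   (e.g. H3K4me3-bearing) loci planted per genome.
#' @param locus_width Width of each marked locus in bp.
#' @param base_occupancy Dimensionless per-locus mark level shared by all
#'   marked loci in the vehicle condition and by the spike-in genome always.
#' @param fold_change Multiplier applied to target-locus occupancy in the
#'   treated condition; spike-in occupancy is never touched (the core
#'   ChIP-Rx assumption).
#' @param pulldown_efficiency Probability that a marked fragment at
#'   occupancy 1 is captured in the pulldown.
#' @param background_capture Probability that an unmarked fragment is
#'   captured in the pulldown (non-specific background).
#' @param depth Number of reads per library.
#'
#' @return An object of class `chiprx_config` (a validated named list).
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, depth = 1000)
#' cfg$read_length
sim_config <- function(seed,
                       n_target_cells = 1e7,
                       n_spikein_cells = 3e6,
                       read_length = 83,
                       paired = FALSE,
                       fragment_length_mean = 300,
                       fragment_length_sd = 50,
                       target_genome_size = 200000,
                       spikein_genome_size = 60000,
                       n_marked_loci_target = 100,
                       n_marked_loci_spikein = 30,
                       locus_width = 500,
                       base_occupancy = 1,
                       fold_change = 1,
                       pulldown_efficiency = 0.25,
                       background_capture = 0.01,
                       depth = 200000) {
  if (missing(seed) || is.null(seed)) {
    stop("'seed' is mandatory in sim_config(); there is no silent default")
  }
  cfg <- list(
    seed = as.integer(seed),
    n_target_cells = n_target_cells,
    n_spikein_cells = n_spikein_cells,
    read_length = as.integer(read_length),
    paired = isTRUE(paired),
    fragment_length_mean = fragment_length_mean,
    fragment_length_sd = fragment_length_sd,
    target_genome_size = as.integer(target_genome_size),
    spikein_genome_size = as.integer(spikein_genome_size),
    n_marked_loci_target = as.integer(n_marked_loci_target),
    n_marked_loci_spikein = as.integer(n_marked_loci_spikein),
    locus_width = as.integer(locus_width),
    base_occupancy = base_occupancy,
    fold_change = fold_change,
    pulldown_efficiency = pulldown_efficiency,
    background_capture = background_capture,
    depth = as.integer(depth)
  )
  class(cfg) <- "chiprx_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "chiprx_config"))
  counts <- c("n_target_cells", "n_spikein_cells", "n_marked_loci_target",
              "n_marked_loci_spikein", "depth")
  for (f in counts) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 0) {
      stop(sprintf("config field '%s' must be a count >= 0", f))
    }
  }
  if (!is.finite(cfg$fold_change) || cfg$fold_change <= 0) {
    stop("fold_change must be > 0")
  }
  for (f in c("pulldown_efficiency", "background_capture")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) {
      stop(sprintf("%s must be a probability in [0,1]", f))
    }
  }
  if (cfg$read_length < 1) stop("read_length must be >= 1")
  if (cfg$fragment_length_mean < cfg$read_length) {
    stop("fragment_length_mean must be >= read_length")
  }
  if (cfg$locus_width < 1) stop("locus_width must be >= 1")
  invisible(cfg)
}

#' Read a simulation/pipeline configuration from a YAML file
#'
#' Unknown keys are rejected so that typos in a run configuration fail
#' loudly rather than silently falling back to defaults.
#'
#' @param path Path to a YAML file whose keys are `sim_config()` arguments.
#' @return A `chiprx_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    stop("unknown config keys: ", paste(bad, collapse = ", "))
  }
  do.call(sim_config, vals)
}

#' @export
print.chiprx_config <- function(x, ...) {
  cat("ChIP-Rx simulation config\n")
  cat(sprintf("  seed: %d   depth: %d reads/library   read length: %d bp\n",
              x$seed, x$depth, x$read_length))
  cat(sprintf("  cells: %g target + %g spike-in\n",
              x$n_target_cells, x$n_spikein_cells))
  cat(sprintf("  genomes: %d bp target / %d bp spike-in; %d + %d marked loci of %d bp\n",
              x$target_genome_size, x$spikein_genome_size,
              x$n_marked_loci_target, x$n_marked_loci_spikein, x$locus_width))
  cat(sprintf("  fold_change: %g   pulldown_efficiency: %g   background: %g\n",
              x$fold_change, x$pulldown_efficiency, x$background_capture))
  invisible(x)
}
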