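test_that("config validation rejects bad parameter values", {
  expect_error(sim_config(), "mandatory")
  expect_error(sim_config(seed = 1, fold_change = 0), "fold_change")
  expect_error(sim_config(seed = 1, pulldown_efficiency = 1.2),
               "probability")
  expect_error(sim_config(seed = 1, depth = -1), "count")
  expect_error(sim_config(seed = 1, fragment_length_mean = 50),
               "read_length")
})

test_that("toy genomes are deterministic and respect sizing limits", {
  cfg <- tiny_config(seed = 11)
  g1 <- build_toy_genomes(cfg)
  g2 <- build_toy_genomes(cfg)
  expect_identical(as.character(g1$target$seqs),
                   as.character(g2$target$seqs))
  expect_identical(as.character(g1$spikein$seqs),
                   as.character(g2$spikein$seqs))
  expect_identical(g1$target$marked_loci, g2$target$marked_loci)

  expect_error(build_toy_genomes(tiny_config(seed = 1,
                                             target_genome_size = 3000,
                                             locus_width = 400)),
               "too small")
  # slots narrower than the locus width cannot hold non-overlapping loci
  expect_error(build_toy_genomes(tiny_config(seed = 1,
                                             n_marked_loci_target = 60)),
               "non-overlapping")
})

test_that("genome base composition is near-uniform (direct count oracle)", {
  cfg <- sim_config(seed = 1, target_genome_size = 100000)
  g <- build_toy_genomes(cfg)
  bases <- strsplit(as.character(g$target$seqs[[1]]), "")[[1]]
  gc <- sum(bases %in% c("G", "C")) / length(bases)
  expect_gt(gc, 0.48)
  expect_lt(gc, 0.52)
})

test_that("zero marked loci gives an empty truth table", {
  g <- build_toy_genomes(tiny_config(seed = 2, n_marked_loci_target = 0))
  expect_identical(nrow(g$target$marked_loci), 0L)
})

test_that("marked loci are non-overlapping, in bounds, of stated width", {
  for (seed in c(3, 4)) {
    cfg <- tiny_config(seed = seed)
    g <- build_toy_genomes(cfg)
    for (gen in g) {
      loci <- gen$marked_loci
      expect_true(all(loci$end - loci$start == cfg$locus_width))
      expect_true(all(loci$start >= 0))
      expect_true(all(loci$end <= sum(Biostrings::width(gen$seqs))))
      expect_true(all(diff(loci$start) >= cfg$locus_width))
    }
  }
})

test_that("simulation is deterministic and reads are internally consistent", {
  cfg <- tiny_config(seed = 21, depth = 500)
  genomes <- build_toy_genomes(cfg)
  libs1 <- simulate_chiprx_experiment(cfg, genomes)
  libs2 <- simulate_chiprx_experiment(cfg, genomes)
  expect_identical(libs1, libs2)
  expect_named(libs1, c("pulldown_treated", "pulldown_vehicle",
                        "input_treated", "input_vehicle"))
  for (lib in libs1) {
    reads <- lib$reads
    expect_identical(nrow(reads), cfg$depth)
    expect_true(all(nchar(reads$sequence) == cfg$read_length))
    # the read sequence must be re-derivable from its truth coordinates
    seqs <- c(as.character(genomes$target$seqs),
              as.character(genomes$spikein$seqs))
    fwd <- unname(substring(seqs[reads$truth_chrom], reads$truth_start + 1L,
                            reads$truth_start + cfg$read_length))
    neg <- reads$truth_strand == "-"
    expect_identical(reads$sequence[!neg], fwd[!neg])
    expect_identical(reads$sequence[neg], rc_chr(fwd[neg]))
  }
})

test_that("input spike-in fraction follows the cell-mixture expectation", {
  # equal genome lengths so the expectation is nspike/(ntarget+nspike)=3/13
  cfg <- tiny_config(seed = 31, target_genome_size = 20000,
                     spikein_genome_size = 20000, depth = 100000)
  genomes <- build_toy_genomes(cfg)
  libs <- simulate_chiprx_experiment(cfg, genomes)
  p <- 3 / 13
  for (lib in libs[c("input_treated", "input_vehicle")]) {
    frac <- mean(lib$reads$truth_genome == "spikein")
    sigma <- sqrt(p * (1 - p) / cfg$depth)
    expect_lt(abs(frac - p), 3 * sigma)
  }
})

test_that("fold_change = 1 leaves target marked-locus read mass symmetric", {
  cfg <- tiny_config(seed = 41, depth = 20000, fold_change = 1)
  genomes <- build_toy_genomes(cfg)
  libs <- simulate_chiprx_experiment(cfg, genomes)
  marked_mass <- function(lib) {
    r <- lib$reads[lib$reads$truth_genome == "target", ]
    loci <- genomes$target$marked_loci
    ov <- outer(r$truth_start, loci$end, `<`) &
      outer(r$truth_start + cfg$read_length, loci$start, `>`)
    sum(rowSums(ov) > 0)
  }
  ratio <- marked_mass(libs$pulldown_treated) /
    marked_mass(libs$pulldown_vehicle)
  expect_gt(ratio, 0.95)
  expect_lt(ratio, 1.05)
})

test_that("pulldown collapses to input when capture is locus-blind", {
  cfg <- tiny_config(seed = 51, depth = 10000, pulldown_efficiency = 0.05,
                     background_capture = 0.05)
  genomes <- build_toy_genomes(cfg)
  libs <- simulate_chiprx_experiment(cfg, genomes)
  classify <- function(lib) {
    r <- lib$reads[lib$reads$truth_genome == "target", ]
    loci <- genomes$target$marked_loci
    ov <- outer(r$truth_start, loci$end, `<`) &
      outer(r$truth_start + cfg$read_length, loci$start, `>`)
    marked <- rowSums(ov) > 0
    c(marked = sum(marked), unmarked = sum(!marked))
  }
  tab <- rbind(classify(libs$pulldown_vehicle),
               classify(libs$input_vehicle))
  p <- stats::chisq.test(tab)$p.value
  expect_gt(p, 0.01)
})

test_that("spike-in read yield is condition-independent", {
  cfg <- tiny_config(seed = 61, depth = 20000, fold_change = 2)
  genomes <- build_toy_genomes(cfg)
  libs <- simulate_chiprx_experiment(cfg, genomes)
  # spike-in composition of the pool is identical across conditions, so the
  # spike counts in equal-depth inputs differ only by sampling noise
  n1 <- sum(libs$input_treated$reads$truth_genome == "spikein")
  n2 <- sum(libs$input_vehicle$reads$truth_genome == "spikein")
  expect_lt(abs(n1 - n2) / sqrt(n1 + n2), 4)
})

test_that("depth 0 warns and yields empty libraries", {
  cfg <- tiny_config(seed = 71, depth = 0)
  genomes <- build_toy_genomes(cfg)
  expect_warning(libs <- simulate_chiprx_experiment(cfg, genomes),
                 "empty")
  expect_identical(nrow(libs$pulldown_treated$reads), 0L)
})

test_that("paired mode emits mates from the opposite fragment end", {
  cfg <- tiny_config(seed = 81, depth = 200, paired = TRUE)
  genomes <- build_toy_genomes(cfg)
  libs <- simulate_chiprx_experiment(cfg, genomes)
  reads <- libs$input_vehicle$reads
  expect_true("mate" %in% names(reads))
  expect_true(all(nchar(reads$mate) == cfg$read_length))
})

test_that("FASTA / FASTQ / BED writers round-trip", {
  cfg <- tiny_config(seed = 91, depth = 50)
  genomes <- build_toy_genomes(cfg)
  libs <- simulate_chiprx_experiment(cfg, genomes)
  fa <- withr::local_tempfile(fileext = ".fa")
  write_genome_fasta(genomes$target, fa)
  back <- read_genome_fasta(fa, "target")
  expect_identical(as.character(back$seqs), as.character(genomes$target$seqs))
  fq <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(libs$input_vehicle, fq)
  rf <- read_fastq(fq)
  expect_identical(rf$sequence, libs$input_vehicle$reads$sequence)
  expect_identical(rf$id, libs$input_vehicle$reads$id)
  bed <- withr::local_tempfile(fileext = ".bed")
  write_truth_bed(genomes$target, bed)
  lines <- strsplit(readLines(bed), "\t")
  expect_identical(as.integer(vapply(lines, `[`, "", 2)),
                   genomes$target$marked_loci$start)
})
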