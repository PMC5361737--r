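test_that("single-read and overlapping-read coverage match the per-base oracle", {
  aln <- make_aln(100, width = 83, chrom_len = 1000)
  tr <- coverage_bedgraph(aln, scale = 2.5)
  expect_equal(tr$intervals$start, 100)
  expect_equal(tr$intervals$end, 183)
  expect_identical(tr$intervals$value, 2.5)

  aln2 <- make_aln(c(0, 40), width = 83, chrom_len = 1000)
  tr2 <- coverage_bedgraph(aln2, scale = 1)
  expect_equal(tr2$intervals$start, c(0, 40, 83))
  expect_equal(tr2$intervals$end, c(40, 83, 123))
  expect_identical(tr2$intervals$value, c(1, 2, 1))
})

test_that("random coverage agrees with the brute-force depth oracle", {
  set.seed(500)
  for (rep in 1:3) {
    n <- 200
    chrom_len <- 2000
    starts <- sample(0:(chrom_len - 30), n, replace = TRUE)
    scale <- stats::runif(1, 0.1, 10)
    aln <- make_aln(starts, width = 30, chrom_len = chrom_len)
    tr <- coverage_bedgraph(aln, scale = scale)
    oracle <- brute_depth(starts, starts + 30, chrom_len) * scale
    rebuilt <- numeric(chrom_len)
    b <- tr$intervals
    for (i in seq_len(nrow(b))) {
      rebuilt[(b$start[i] + 1):b$end[i]] <- b$value[i]
    }
    expect_equal(rebuilt, oracle)
    # mass conservation against the oracle's own total
    expect_equal(track_total <- sum(b$value * (b$end - b$start)),
                 sum(oracle))
  }
})

test_that("empty alignments give an empty track; bad bounds error", {
  idx <- make_index(c(chr1 = rand_dna(500)), c(sf1 = rand_dna(300)))
  empty <- assign_reads(data.frame(id = character(),
                                   sequence = character()), idx)$alignments
  tr <- coverage_bedgraph(empty, scale = 1)
  expect_identical(nrow(tr$intervals), 0L)
  bad <- suppressWarnings(make_aln(990, width = 83, chrom_len = 1000))
  expect_error(coverage_bedgraph(bad, scale = 1),
               "outside chromosome bounds")
})

test_that("strand mode restricts coverage to one strand", {
  plus <- make_aln(c(0, 100), width = 50, chrom_len = 1000, strand = "+")
  minus <- make_aln(c(200, 300), width = 50, chrom_len = 1000, strand = "-")
  both <- c(plus, minus)
  GenomeInfoDb::seqlengths(both) <- GenomeInfoDb::seqlengths(plus)
  tp <- coverage_bedgraph(both, 1, strand_mode = "+")
  tm <- coverage_bedgraph(both, 1, strand_mode = "-")
  expect_equal(tp$intervals$start, c(0, 100))
  expect_equal(tm$intervals$start, c(200, 300))
  expect_identical(tp$aligned_bases + tm$aligned_bases,
                   coverage_bedgraph(both, 1)$aligned_bases)
})

test_that("bedGraph write/read round-trips intervals and values exactly", {
  set.seed(501)
  aln <- make_aln(sample(0:900, 80, TRUE), width = 60, chrom_len = 1000)
  tr <- coverage_bedgraph(aln, scale = 1 / 739123)  # awkward float
  path <- withr::local_tempfile(fileext = ".bedgraph")
  write_bedgraph(tr, path, header = TRUE)
  back <- read_bedgraph(path, tr$sample_id, tr$strand, tr$normalization,
                        tr$scale, tr$aligned_bases, tr$seqlengths)
  expect_identical(back$intervals$value, tr$intervals$value)
  expect_identical(back$intervals$start, as.integer(tr$intervals$start))
  expect_identical(back$intervals$end, as.integer(tr$intervals$end))
})

test_that("rpm and spikein tracks of one sample are exactly proportional", {
  set.seed(502)
  aln <- make_aln(sample(0:900, 100, TRUE), width = 50, chrom_len = 1000)
  scale_spike <- 3.7e-6
  scale_rpm <- 0.05
  a <- coverage_bedgraph(aln, scale_spike, normalization = "spikein")
  b <- coverage_bedgraph(aln, scale_rpm, normalization = "rpm")
  expect_identical(a$intervals$start, b$intervals$start)
  expect_equal(a$intervals$value / b$intervals$value,
               rep(scale_spike / scale_rpm, nrow(a$intervals)))
})

test_that("metagene: uniform coverage gives a flat profile", {
  # one giant read-like interval covering everything at value c
  sl <- c("target|chr1" = 10000L)
  tr <- coverage_track(
    data.frame(chrom = "target|chr1", start = 0, end = 10000, value = 4.2),
    "s", "both", "raw", scale = 4.2, aligned_bases = 10000, seqlengths = sl)
  tss <- data.frame(chrom = "target|chr1", pos = c(3000, 5000, 7000),
                    strand = c("+", "-", "+"))
  mg <- metagene_tss(tr, tss, window = 1000, bin = 25)
  expect_identical(mg$n_sites, 3L)
  expect_true(all(mg$values == 4.2))
})

test_that("metagene recovers a planted symmetric peak on both strands", {
  sl <- c("target|chr1" = 20000L)
  peak <- function(center) {
    # triangular peak of half-width 200 centred on `center` (0-based)
    pos <- (center - 200):(center + 199)
    data.frame(chrom = "target|chr1", start = pos, end = pos + 1,
               value = 200 - abs(pos + 0.5 - center))
  }
  mk_track <- function(center) {
    b <- peak(center)
    coverage_track(b, "s", "both", "raw", scale = 1,
                   aligned_bases = sum(b$value), seqlengths = sl)
  }
  tr_plus <- mk_track(5000)
  mg_plus <- metagene_tss(tr_plus,
                          data.frame(chrom = "target|chr1", pos = 5000,
                                     strand = "+"),
                          window = 1000, bin = 25)
  peak_bin <- which.max(mg_plus$values)
  # the maximum must sit in a bin whose span contains offset 0
  expect_lte(abs(mg_plus$offsets[peak_bin]), 25 / 2)

  tr_minus <- mk_track(9000)
  mg_minus <- metagene_tss(tr_minus,
                           data.frame(chrom = "target|chr1", pos = 9000,
                                      strand = "-"),
                           window = 1000, bin = 25)
  # strand symmetry: a symmetric peak looks identical after flipping
  expect_equal(mg_minus$values, mg_plus$values)
})

test_that("metagene skips out-of-bounds sites and validates arguments", {
  sl <- c("target|chr1" = 5000L)
  tr <- coverage_track(
    data.frame(chrom = "target|chr1", start = 0, end = 5000, value = 1),
    "s", "both", "raw", 1, 5000, sl)
  tss <- data.frame(chrom = "target|chr1", pos = c(100, 2500),
                    strand = c("+", "+"))
  mg <- metagene_tss(tr, tss, window = 1000, bin = 100)
  expect_identical(mg$n_sites, 1L)
  expect_identical(mg$n_skipped, 1L)
  expect_error(metagene_tss(tr, tss, window = 1000, bin = 300), "multiple")
  expect_error(metagene_tss(tr, tss[0, ], 1000, 100), "non-empty")
})

test_that("peak_mean_coverage matches per-base expectations", {
  sl <- c("target|chr1" = 1000L)
  tr <- coverage_track(
    data.frame(chrom = "target|chr1", start = c(100, 150), end = c(150, 200),
               value = c(0, 2))[-1, ],  # value 2 over [150,200) only
    "s", "both", "raw", 1, 100, sl)
  const <- peak_mean_coverage(tr, data.frame(chrom = "target|chr1",
                                             start = 150, end = 200))
  expect_identical(const$overall_mean, 2)
  half <- peak_mean_coverage(tr, data.frame(chrom = "target|chr1",
                                            start = 100, end = 200))
  expect_identical(half$overall_mean, 1)  # half 0, half 2
  outside <- peak_mean_coverage(tr, data.frame(chrom = "target|chr1",
                                               start = 500, end = 600))
  expect_identical(outside$overall_mean, 0)
  expect_error(peak_mean_coverage(tr, data.frame()), "empty")
})

test_that("track construction rejects overlap and mass violations", {
  sl <- c("target|chr1" = 1000L)
  expect_error(coverage_track(
    data.frame(chrom = "target|chr1", start = c(0, 50), end = c(100, 150),
               value = 1), "s", "both", "raw", 1, 200, sl),
    "overlap")
  expect_error(coverage_track(
    data.frame(chrom = "target|chr1", start = 0, end = 100, value = 1),
    "s", "both", "raw", scale = 1, aligned_bases = 999, seqlengths = sl),
    "mass")
})
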