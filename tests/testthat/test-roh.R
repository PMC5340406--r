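test_that("qc_filter keeps a clean polymorphic matrix unchanged", {
  set.seed(1)
  calls <- matrix(sample(0:2, 200, replace = TRUE, prob = c(0.49, 0.42, 0.09)),
                  nrow = 20)
  # force every marker to a comfortable MAF around 0.3
  gm <- toy_gm(calls)
  maf <- pmin(rowMeans(calls) / 2, 1 - rowMeans(calls) / 2)
  gm2 <- qc_filter(gm)
  kept <- maf > 0.05
  expect_equal(nrow(gm2$markers), sum(kept))
  expect_identical(gm2$calls, gm$calls[kept, , drop = FALSE])
})

test_that("qc_filter removes monomorphic and low-call-rate markers (hand-computed toy)", {
  # 5 markers x 5 samples: marker 4 monomorphic (MAF 0), marker 5 with
  # 2/5 missing (call rate 0.6); relaxed sample threshold keeps samples
  calls <- rbind(c(0, 1, 2, 1, 0),
                 c(1, 0, 1, 2, 1),
                 c(2, 1, 0, 0, 1),
                 c(0, 0, 0, 0, 0),
                 c(NA, 1, NA, 0, 1))
  gm <- toy_gm(calls)
  th <- qc_thresholds(min_snp_call_rate = 0.95, min_sample_call_rate = 0.5,
                      min_maf = 0.05)
  out <- qc_filter(gm, th)
  expect_equal(out$markers$id, gm$markers$id[1:3])
  expect_equal(length(out$samples), 5)
  log <- attr(out, "qc_log")
  expect_equal(log$n_markers_low_call_rate, 1)
  expect_equal(log$n_markers_low_maf, 1)   # the monomorphic marker
  expect_equal(log$n_markers_removed, 2)
})

test_that("qc_filter is idempotent", {
  set.seed(42)
  for (rep in 1:5) {
    calls <- matrix(sample(c(0:2, NA), 600, replace = TRUE,
                           prob = c(0.4, 0.3, 0.2, 0.1)), nrow = 60)
    gm <- toy_gm(calls)
    once <- try(qc_filter(gm), silent = TRUE)
    if (inherits(once, "try-error")) next
    twice <- qc_filter(once)
    expect_identical(once$calls, twice$calls)
    expect_identical(once$markers, twice$markers)
  }
})

test_that("an all-heterozygous sample yields no ROH", {
  gm <- toy_gm(matrix(1L, nrow = 300, ncol = 1))
  expect_equal(nrow(detect_roh(gm, "s1", roh_params())), 0)
})

test_that("detect_roh errors on an unknown sample", {
  gm <- toy_gm(matrix(0L, nrow = 10, ncol = 1))
  expect_error(detect_roh(gm, "nope"), "unknown sample")
})

test_that("a single homozygous block is recovered with window-bounded edges", {
  g <- rep(1L, 300)
  g[76:225] <- 0L
  pos <- seq_len(300) * 10000L
  gm <- toy_gm(matrix(g, ncol = 1), pos = pos)
  par <- roh_params(window_snps = 20, max_het_per_window = 0,
                    max_missing_per_window = 0, window_hit_threshold = 0.05,
                    min_segment_snps = 50, min_segment_kb = 100,
                    min_density_kb_per_snp = 100, max_gap_kb = 1000)
  seg <- detect_roh(gm, "s1", par)
  expect_equal(nrow(seg), 1)
  expect_lte(abs(seg$start_bp - pos[76]), par$window_snps * 10000)
  expect_lte(abs(seg$end_bp - pos[225]), par$window_snps * 10000)
  # and the segment equals the exhaustive-window oracle exactly
  orc <- oracle_detect_roh(g, pos, par)
  expect_equal(seg$start_bp, orc$start)
  expect_equal(seg$end_bp, orc$end)
  expect_equal(seg$n_snps, orc$n)
})

test_that("detect_roh equals the exhaustive-window oracle on random small matrices", {
  set.seed(2024)
  par <- roh_params(window_snps = 10, max_het_per_window = 1,
                    max_missing_per_window = 2, window_hit_threshold = 0.05,
                    min_segment_snps = 20, min_segment_kb = 10,
                    min_density_kb_per_snp = 100, max_gap_kb = 200)
  for (rep in 1:25) {
    n <- sample(50:500, 1)
    # blocky genotypes: alternating het-rich and hom-rich stretches
    g <- integer(0)
    while (length(g) < n) {
      len <- sample(10:80, 1)
      hom <- runif(1) < 0.5
      block <- if (hom) sample(c(0L, 2L, 1L, NA), len, replace = TRUE,
                               prob = c(0.55, 0.38, 0.04, 0.03))
               else sample(c(0L, 1L, 2L, NA), len, replace = TRUE,
                           prob = c(0.3, 0.4, 0.25, 0.05))
      g <- c(g, block)
    }
    g <- g[seq_len(n)]
    pos <- sort(sample.int(n * 5000L, n))
    gm <- toy_gm(matrix(g, ncol = 1), pos = pos)
    seg <- detect_roh(gm, "s1", par)
    orc <- oracle_detect_roh(g, pos, par)
    expect_equal(nrow(seg), nrow(orc))
    if (nrow(orc) > 0) {
      expect_equal(seg$start_bp, orc$start)
      expect_equal(seg$end_bp, orc$end)
      expect_equal(seg$n_snps, orc$n)
    }
  }
})

test_that("noiseless case ROH covers the planted interval almost completely", {
  cfg <- sim_config(genotyping_error_rate = 0, missing_rate = 0, seed = 31)
  arr <- simulate_array_genotypes(config = cfg)
  gm <- qc_filter(arr$genotypes)
  roh <- cfg$planted_roh
  seg <- detect_roh(gm, "case1")
  seg <- seg[seg$chrom == roh$contig, ]
  cov <- sum(pmax(0, pmin(seg$end_bp, roh$end_bp) -
                     pmax(seg$start_bp, roh$start_bp) + 1))
  expect_gte(cov / (roh$end_bp - roh$start_bp + 1), 0.99)
})

test_that("shared_regions returns a single case's segments verbatim", {
  gm <- toy_gm(matrix(0L, nrow = 10, ncol = 1), samples = "case1")
  segs <- data.frame(sample = "case1", chrom = "chr1",
                     start_bp = c(1000L, 9000L), end_bp = c(3000L, 10000L),
                     n_snps = c(3L, 2L), n_het = 0L, n_missing = 0L,
                     kb = c(2, 1))
  out <- shared_regions(list(case1 = segs), gm)
  expect_equal(out$start_bp, segs$start_bp)
  expect_equal(out$end_bp, segs$end_bp)
  expect_equal(out$n_cases_supporting, c(1L, 1L))
})

test_that("two-case overlap intersects intervals when alleles match", {
  pos <- seq(1e6, 15e6, by = 1e5)
  calls <- matrix(2L, nrow = length(pos), ncol = 2)
  gm <- toy_gm(calls, pos = pos, samples = c("case1", "case2"))
  seg1 <- data.frame(sample = "case1", chrom = "chr1", start_bp = 1e6,
                     end_bp = 10e6, n_snps = 91L, n_het = 0L, n_missing = 0L,
                     kb = 9000)
  seg2 <- seg1
  seg2$sample <- "case2"; seg2$start_bp <- 5e6; seg2$end_bp <- 15e6
  out <- shared_regions(list(case1 = seg1, case2 = seg2), gm)
  expect_equal(nrow(out), 1)
  expect_equal(out$start_bp, 5e6)
  expect_equal(out$end_bp, 10e6)
  expect_equal(out$n_cases_supporting, 2L)
})

test_that("opposite homozygous alleles abolish the shared region", {
  pos <- seq(1e6, 10e6, by = 1e5)
  calls <- cbind(rep(0L, length(pos)), rep(2L, length(pos)))
  gm <- toy_gm(calls, pos = pos, samples = c("case1", "case2"))
  seg <- data.frame(sample = "case1", chrom = "chr1", start_bp = 1e6,
                    end_bp = 10e6, n_snps = length(pos), n_het = 0L,
                    n_missing = 0L, kb = 9000)
  seg2 <- seg; seg2$sample <- "case2"
  out <- shared_regions(list(case1 = seg, case2 = seg2), gm)
  expect_equal(nrow(out), 0)
})

test_that("empty segment input gives an empty region list, not an error", {
  gm <- toy_gm(matrix(0L, nrow = 5, ncol = 1), samples = "case1")
  empty <- detect_roh(gm, "case1")  # 5 markers < window: empty
  out <- shared_regions(list(case1 = empty), gm)
  expect_equal(nrow(out), 0)
})

test_that("adding a case never enlarges the shared span (funnel monotonicity)", {
  cfg <- sim_config(genotyping_error_rate = 0, missing_rate = 0, seed = 37)
  arr <- simulate_array_genotypes(config = cfg)
  gm <- qc_filter(arr$genotypes)
  cases <- paste0("case", 1:4)
  segs <- lapply(setNames(cases, cases), function(s) detect_roh(gm, s))
  span <- function(reg) sum(reg$end_bp - reg$start_bp + 1)
  spans <- vapply(2:4, function(k)
    span(shared_regions(segs[seq_len(k)], gm)), numeric(1))
  expect_true(all(diff(spans) <= 0))
})
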