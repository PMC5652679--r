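test_that("HWE exact test matches direct-factorial enumeration exhaustively", {
  # every genotype configuration with up to 50 subjects
  for (n in c(1:20, 30, 40, 50)) {
    for (n_aa in 0:n) for (n_het in 0:(n - n_aa)) {
      n_AA <- n - n_aa - n_het
      expect_equal(hwe_exact_test(n_AA, n_het, n_aa),
                   oracle_hwe(n_AA, n_het, n_aa),
                   tolerance = 1e-10,
                   label = sprintf("hwe(%d,%d,%d)", n_AA, n_het, n_aa))
    }
  }
})

test_that("HWE exact test handles canonical cases", {
  expect_equal(hwe_exact_test(100, 0, 0), 1)           # monomorphic
  expect_equal(hwe_exact_test(1, 2, 1), oracle_hwe(1, 2, 1))
  # near-equilibrium counts: 138 hets vs ~141 expected, p well above 0.05
  p <- hwe_exact_test(1469, 138, 5)
  expect_equal(p, oracle_hwe(1469, 138, 5), tolerance = 1e-10)
  expect_gt(p, 0.05)
  # gross heterozygote deficit is detected
  expect_lt(hwe_exact_test(50, 0, 50), 1e-6)
  expect_error(hwe_exact_test(0, 0, 0), "no genotypes")
  expect_error(hwe_exact_test(-1, 2, 1), "nonnegative")
})

test_that("marker and sample statistics count correctly", {
  g <- toy_genotypes(rbind(c(0L, 0L, 1L), c(0L, 1L, 1L),
                           c(1L, 1L, 1L), c(NA, 2L, NA)))
  ms <- marker_stats(g)
  expect_equal(ms$call_rate, c(0.75, 1, 0.75))
  expect_equal(ms$maf[1], 1 / 6)                        # folded
  expect_equal(ms$maf[2], 0.5)                          # [0,1,1,2]
  expect_false(any(ms$monomorphic))
  g2 <- toy_genotypes(matrix(0L, 3, 1))
  ms2 <- marker_stats(g2)
  expect_true(ms2$monomorphic)
  expect_equal(ms2$maf, 0)
  expect_equal(ms2$hwe_p, 1)

  ss <- sample_stats(g)
  expect_equal(ss$call_rate, c(1, 1, 1, 1 / 3))
  expect_equal(ss$heterozygosity, c(1 / 3, 2 / 3, 1, 0))
  g3 <- toy_genotypes(rbind(c(1L, 1L, 1L), c(NA, NA, NA)))
  ss3 <- sample_stats(g3)
  expect_equal(ss3$heterozygosity, c(1, NA))
  expect_equal(ss3$call_rate, c(1, 0))
})

test_that("apply_qc removes markers for the documented reasons", {
  set.seed(5)
  n <- 200; m <- 40   # wide enough that one missing call keeps a
                      # sample's own call rate above the sample screen
  counts <- vapply(rep(0.3, m), function(q)
    sample(0:2, n, TRUE, c((1 - q)^2, 2 * q * (1 - q), q^2)),
    integer(n))
  # marker 1: 6% missing calls
  counts[sample(n, 12), 1] <- NA
  # marker 2: gross HWE violation (all heterozygous)
  counts[, 2] <- 1L
  # marker 3: monomorphic
  counts[, 3] <- 0L
  g <- toy_genotypes(counts)
  qc <- apply_qc(g)
  # a handful of heterozygosity outliers may go; the marker screen is
  # what this fixture exercises
  expect_gte(qc$summary$n_samples_after, n - 8)
  expect_equal(qc$markers$reason[1], "call_rate")
  expect_equal(qc$markers$reason[2], "hwe")
  expect_lt(qc$markers$hwe_p[2], 1e-6)
  expect_equal(qc$markers$reason[3], "monomorphic")
  expect_true(all(qc$markers$kept[4:m]))
  expect_equal(qc$summary$n_markers_after, m - 3)
})

test_that("sample screens act on call rate, heterozygosity and duplicates", {
  set.seed(8)
  n <- 100; m <- 60
  counts <- vapply(rep(0.25, m), function(q)
    sample(0:2, n, TRUE, c((1 - q)^2, 2 * q * (1 - q), q^2)),
    integer(n))
  counts[1, seq_len(m * 0.1)] <- NA      # sample 1: 90% call rate
  counts[2, ] <- 1L                      # sample 2: heterozygosity 1
  counts[4, ] <- counts[3, ]             # duplicated pair 3/4
  counts[4, 1] <- NA                     # member 4 has lower call rate
  g <- toy_genotypes(counts)
  qc <- apply_qc(g)
  expect_equal(qc$samples$reason[1], "call_rate")
  expect_equal(qc$samples$reason[2], "heterozygosity")
  expect_equal(qc$samples$reason[4], "relatedness")
  expect_true(qc$samples$kept[3])        # higher-call-rate member kept
})

test_that("permissive thresholds leave the cohort untouched", {
  set.seed(3)
  co <- simulate_cohort(simulation_config(n_samples = 120, seed = 3))
  th <- qc_thresholds(marker_max_missing = 0.99,
                      sample_min_call_rate = 0.01, hwe_alpha = 0,
                      het_sd_limit = 100, relatedness_max_ibs_prop = 2,
                      drop_monomorphic = FALSE)
  qc <- apply_qc(co$genotypes, th)
  expect_identical(qc$genotypes$counts, co$genotypes$counts)
})

test_that("apply_qc is idempotent on simulated cohorts", {
  for (seed in c(1, 7)) {
    co <- simulate_cohort(simulation_config(n_samples = 250, seed = seed,
                                            missing_rate = 0.02))
    q1 <- apply_qc(co$genotypes)
    q2 <- apply_qc(q1$genotypes)
    expect_identical(q2$genotypes$counts, q1$genotypes$counts)
  }
})

test_that("loosening any threshold never removes more units", {
  co <- simulate_cohort(simulation_config(n_samples = 200, seed = 12,
                                          missing_rate = 0.03))
  base <- qc_thresholds()
  kept <- function(th) {
    q <- apply_qc(co$genotypes, th)
    c(q$summary$n_samples_after, q$summary$n_markers_after)
  }
  k0 <- kept(base)
  # marker thresholds: sample stage untouched, marker count monotone
  for (th in list(qc_thresholds(marker_max_missing = 0.2),
                  qc_thresholds(hwe_alpha = 1e-12))) {
    k <- kept(th)
    expect_equal(k[1], k0[1])
    expect_gte(k[2], k0[2])
  }
  # sample thresholds: sample count monotone (marker stats are then
  # recomputed on a different sample set, so marker counts may shift)
  for (th in list(qc_thresholds(sample_min_call_rate = 0.5),
                  qc_thresholds(het_sd_limit = 10),
                  qc_thresholds(relatedness_max_ibs_prop = 0.9)))
    expect_gte(kept(th)[1], k0[1])
})

test_that("emptying QC warns rather than failing silently", {
  g <- toy_genotypes(matrix(c(0L, 0L, 0L, 0L), 2, 2))
  expect_warning(qc <- apply_qc(g), "all markers removed")
  expect_equal(qc$summary$n_markers_after, 0)
})
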