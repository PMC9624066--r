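test_that("signed-rank p-values match the exact null", {
  ## all 21 participants above chance: p = 2^-21
  acc <- matrix(0.5 + runif(21, 0.01, 0.2), 21, 1)
  p <- wilcoxon_above_chance(acc)
  expect_equal(p[1], 2^-21, tolerance = 1e-12)

  ## n = 5 hand vector vs exhaustive enumeration of all 2^5 sign patterns
  v <- c(0.6, 0.7, 0.55, 0.52, 0.65)
  p5 <- wilcoxon_above_chance(matrix(v, 5, 1))
  expect_equal(p5[1], signed_rank_exact_oracle(v - 0.5))

  ## random configurations against the oracle
  set.seed(30)
  for (i in 1:10) {
    d <- round(rnorm(7), 3)
    d <- d[d != 0]
    pw <- wilcoxon_above_chance(matrix(0.5 + d, length(d), 1))
    expect_equal(pw[1], signed_rank_exact_oracle(d), tolerance = 1e-10)
  }

  ## all-zero differences: p = 1 by convention
  pz <- wilcoxon_above_chance(matrix(0.5, 6, 2))
  expect_equal(as.vector(pz), c(1, 1), ignore_attr = TRUE)
  expect_equal(attr(pz, "n_zero"), c(6L, 6L))

  expect_error(wilcoxon_above_chance(matrix(0.6, 3, 2)), ">= 5")
})

test_that("accuracies symmetric around chance give uniform-centred p", {
  set.seed(31)
  ps <- replicate(60, wilcoxon_above_chance(matrix(0.5 + rnorm(10, 0, 0.05),
                                                   10, 1))[1])
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps), 0.65)
})

test_that("Benjamini-Hochberg step-up follows the hand rule", {
  m <- fdr_correct(rep(0.001, 8), q = 0.05)
  expect_true(all(m$mask))

  m2 <- fdr_correct(c(0.01, 0.02, 0.03, 0.5), q = 0.05)
  expect_equal(m2$mask, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(m2$p_adj, p.adjust(c(0.01, 0.02, 0.03, 0.5), "BH"))

  expect_error(fdr_correct(numeric(0)), "empty")
  expect_error(fdr_correct(c(0.5, 1.2)), "0, 1")
})

test_that("null FDR discovery fraction is controlled on average", {
  set.seed(32)
  fracs <- replicate(200, {
    mean(fdr_correct(runif(50), q = 0.05)$mask)
  })
  expect_lte(mean(fracs), 0.05)
})

test_that("onset latency requires a sustained run from stimulus onset", {
  tm <- seq(-100, 600)
  mk <- function(idx) { m <- rep(FALSE, length(tm)); m[idx] <- TRUE; m }
  ## run of exactly 14 -> undefined
  expect_true(is.na(onset_latency(mk(which(tm >= 120 & tm <= 133)), tm, 15)))
  ## run of 15 starting at 120 -> 120
  expect_equal(onset_latency(mk(which(tm >= 120 & tm <= 134)), tm, 15), 120)
  ## pre-stimulus runs are ignored
  expect_true(is.na(onset_latency(mk(which(tm >= -90 & tm <= -50)), tm, 15)))

  ## random masks vs exhaustive window scan
  brute <- function(m, tms, k) {
    for (i in seq_len(length(m) - k + 1)) {
      if (tms[i] >= 0 && all(m[i:(i + k - 1)])) return(tms[i])
    }
    NA_real_
  }
  set.seed(33)
  for (i in 1:50) {
    m <- runif(80) < 0.45
    tms <- seq(-20, 59)
    expect_identical(onset_latency(m, tms, 5), brute(m, tms, 5))
  }
})

test_that("peak latency takes the earliest global maximum", {
  tm <- 0:10
  expect_equal(peak_latency(seq(0, 1, length.out = 11), tm), 10)
  curve <- c(0, 1, 3, 3, 2, 0, 0, 0, 0, 0, 0)
  expect_equal(peak_latency(curve, tm), 2)
  ## window restriction
  expect_equal(peak_latency(curve, tm, window = c(4, 10)), 4)
})

test_that("participant bootstrap is seeded, smoothed and anchor-correct", {
  ## identical values: zero-width CI
  b <- bootstrap_participants(matrix(2, 8, 1), function(d) mean(d),
                              n_boot = 50, seed = 1)
  expect_equal(b$ci, c(2, 2))
  ## determinism
  x <- matrix(rnorm(16), 8, 2)
  b1 <- bootstrap_participants(x, function(d) mean(d[, 1] - d[, 2]),
                               n_boot = 10, seed = 7)
  b2 <- bootstrap_participants(x, function(d) mean(d[, 1] - d[, 2]),
                               n_boot = 10, seed = 7)
  expect_identical(b1$distribution, b2$distribution)
  ## CI excluding 0 <-> p < 0.05 (up to +1 smoothing) on a shifted sample
  set.seed(34)
  y <- matrix(rnorm(12, mean = 1), 12, 1)
  bs <- bootstrap_participants(y, mean, n_boot = 400, seed = 2)
  expect_true((bs$ci[1] > 0) == (bs$p < 0.05 + 2 / 401))
  ## undefined statistic on most resamples aborts
  expect_error(
    bootstrap_participants(matrix(1:6, 6, 1), function(d) NA_real_,
                           n_boot = 20, seed = 3),
    "undefined"
  )
})

test_that("condition-label permutation test matches its exhaustive null", {
  m <- matrix(0, 4, 4)
  m[upper.tri(m)] <- c(0.2, 0.5, 0.9, 0.4, 0.8, 0.6)
  a <- rdm(m + t(m), 1:4)
  m2 <- matrix(0, 4, 4)
  m2[upper.tri(m2)] <- c(0.25, 0.45, 0.85, 0.5, 0.75, 0.55)
  b <- rdm(m2 + t(m2), 1:4)

  ex <- permutation_rdm_test(a, b, exhaustive = TRUE)
  expect_equal(length(ex$null), 24)
  ## sampled null converges to the exhaustive null distribution
  sam <- permutation_rdm_test(a, b, n_perm = 2000, seed = 4)
  expect_lt(abs(mean(sam$null >= ex$rho - 1e-12) - ex$p), 0.03)

  ## identical non-degenerate RDMs: rho 1, minimal p
  same <- permutation_rdm_test(a, a, n_perm = 200, seed = 5)
  expect_equal(same$rho, 1)
  expect_lte(same$p, 0.05)

  bad <- rdm(m2 + t(m2), c(2, 1, 3, 4))
  expect_error(permutation_rdm_test(a, bad, n_perm = 10), "do not match")
})

test_that("significance timecourse extracts latencies from decoding results", {
  ## synthetic decoding_result with a known significance window
  tm <- seq(0, 200, by = 10)
  set.seed(35)
  acc <- array(0.5, dim = c(8, 1, length(tm)))
  sig_idx <- tm >= 80 & tm <= 160
  acc[, 1, sig_idx] <- 0.8 + rnorm(sum(sig_idx) * 8, 0, 0.01)
  acc[, 1, !sig_idx] <- 0.5 + rnorm(sum(!sig_idx) * 8, 0, 0.01)
  res <- structure(list(accuracy = acc, categories = "face", time_ms = tm,
                        scheme = "category_selectivity",
                        params = decoding_params(),
                        participant_ids = sprintf("s%02d", 1:8)),
                   class = "decoding_result")
  sig <- significance_timecourse(res, min_run = 3)
  expect_equal(sig$onset_ms, 80)
  expect_true(sig$peak_ms >= 80 && sig$peak_ms <= 160)
})
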