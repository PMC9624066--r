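test_that("condition means average repetitions in canonical order", {
  labs <- data.frame(condition_id = c(2, 1, 2, 1))
  x <- matrix(c(1, 2, 3, 4,
                5, 6, 7, 8), 4, 2)
  cm <- condition_means(x, labs)
  expect_equal(attr(cm, "condition_order"), c(1, 2))
  expect_equal(cm[1, ], c(mean(c(2, 4)), mean(c(6, 8))))
  ## permuted trial order gives identical output
  perm <- c(3, 1, 4, 2)
  cm2 <- condition_means(x[perm, ], labs[perm, , drop = FALSE])
  expect_equal(unname(cm2), unname(cm))
  ## single trial per condition: identity mapping
  labs1 <- data.frame(condition_id = 1:4)
  expect_equal(unname(condition_means(x, labs1)), unname(x), ignore_attr = TRUE)
})

test_that("condition means converge at the central-limit rate", {
  set.seed(20)
  truth <- c(3, -1, 2)
  devs <- replicate(50, {
    x <- matrix(rep(truth, each = 32), 32, 3) + matrix(rnorm(96), 32, 3)
    cm <- condition_means(x, data.frame(condition_id = rep(1, 32)))
    max(abs(cm - truth))
  })
  expect_lt(mean(devs), 4 / sqrt(32))
})

test_that("RDM entries equal 1 minus Spearman correlation", {
  pat <- rbind(c(1, 2, 3, 4),
               c(4, 3, 2, 1),
               c(2, 1, 4, 3))
  r <- compute_rdm(pat)
  expect_true(is.nan(r[1, 1]))
  expect_equal(r[1, 2], 2)  # exactly reversed ranks
  ## brute-force rank oracle for every off-diagonal pair
  for (i in 1:2) for (j in (i + 1):3) {
    expect_equal(r[i, j], 1 - spearman_oracle(pat[i, ], pat[j, ]))
    expect_equal(r[i, j], r[j, i])
  }
  ## identical patterns are zero-dissimilar
  r2 <- compute_rdm(rbind(c(1, 5, 2, 8), c(1, 5, 2, 8), c(9, 1, 3, 2)))
  expect_equal(r2[1, 2], 0)

  expect_warning(compute_rdm(rbind(c(1, 1, 1), c(1, 2, 3))), "constant")
  expect_error(compute_rdm(matrix(1:4, 2, 2)), "3 features")
})

test_that("RDM objects enforce symmetry, range and condition order", {
  m <- matrix(c(0, 0.5, 0.5, 0), 2, 2)
  r <- rdm(m, c(10, 20))
  expect_true(all(is.nan(diag(r))))
  expect_error(rdm(matrix(c(0, 0.4, 0.5, 0), 2, 2), 1:2), "symmetric")
  expect_error(rdm(matrix(c(0, 3, 3, 0), 2, 2), 1:2), "0, 2")
  expect_error(rdm(m, c(1, 1)), "duplicates")
  expect_equal(rdm_utv(r), 0.5)
})

test_that("time-resolved RDM stacks average participants elementwise", {
  des <- tiny_design(n_repetitions = 2)
  p <- tiny_params(n_participants = 2, n_repetitions = 2)
  eeg <- simulate_eeg(p, des)
  stack <- rdm_timecourse(eeg)
  n_t <- length(eeg[[1]]$time_ms)
  expect_equal(dim(stack$values), c(50, 50, n_t))
  ## two identical participants: group mean equals either
  stack1 <- rdm_timecourse(eeg[[1]])
  twin <- rdm_timecourse(list(eeg[[1]], eeg[[1]]))
  expect_equal(twin$values, stack1$values)
  ## every produced RDM is symmetric with NaN diagonal
  r5 <- rdm_at(stack, 5)
  expect_true(all(is.nan(diag(r5))))
  expect_equal(unclass(r5), t(unclass(r5)))
})

test_that("pre-onset RDMs of noise-only data fluctuate around 1", {
  des <- make_design(5, 5, 1, n_repetitions = 2)
  amps0 <- setNames(rep(0, 5), nf_categories)
  p <- generator_params(n_participants = 1, n_channels = 10, sfreq = 50,
                        epoch_window = c(0, 200), n_repetitions = 2,
                        category_amplitudes = amps0, seed = 21)
  stack <- rdm_timecourse(simulate_eeg(p, des))
  m <- mean(stack$values[, , 1][upper.tri(stack$values[, , 1])])
  expect_gt(m, 0.9)
  expect_lt(m, 1.1)
})

test_that("regional RDMs with one all-electrode region equal the pooled stack", {
  des <- tiny_design(n_repetitions = 2)
  p <- tiny_params(sfreq = 500, epoch_window = c(0, 200), n_repetitions = 2,
                   ecog_electrodes = c("O-Inf" = 6))
  ecog <- simulate_ecog(p, des)
  pooled <- rdm_timecourse(ecog)
  reg <- regional_rdms(ecog)
  expect_equal(reg[["O-Inf"]]$values, pooled$values)
  ## warnings for thin regions; empty regions skipped
  expect_warning(regional_rdms(ecog, regions = c("O-Inf", "T-Pole")), "skipped")
})

test_that("the upper noise ceiling behaves at its anchors", {
  ord <- 1:4
  mk <- function(utv) {
    m <- matrix(0, 4, 4)
    m[upper.tri(m)] <- utv
    rdm(m + t(m), ord)
  }
  a <- mk(c(0.1, 0.4, 0.9, 0.5, 1.3, 0.8) / 2)
  ## identical participants: ceiling exactly 1
  expect_equal(noise_ceiling_upper(list(a, a, a)), 1)

  ## rank-reversed pair: brute-force oracle value
  b <- mk(rev(c(0.1, 0.4, 0.9, 0.5, 1.3, 0.8) / 2))
  group <- (rdm_utv(a) + rdm_utv(b)) / 2
  oracle <- mean(c(cor(rdm_utv(a), group, method = "spearman"),
                   cor(rdm_utv(b), group, method = "spearman")))
  expect_equal(noise_ceiling_upper(list(a, b)), oracle)
  expect_lt(noise_ceiling_upper(list(a, b)), 1)

  ## independent random RDMs: positive self-inclusion bias, above the
  ## leave-one-out variant
  set.seed(22)
  bias <- replicate(50, {
    rdms <- lapply(1:4, function(i) mk(runif(6)))
    utvs <- sapply(rdms, rdm_utv)
    loo <- mean(sapply(1:4, function(i) {
      cor(utvs[, i], rowMeans(utvs[, -i]), method = "spearman")
    }))
    c(ceiling = noise_ceiling_upper(rdms), loo = loo)
  })
  expect_gt(mean(bias["ceiling", ]), 0)
  expect_gt(mean(bias["ceiling", ] - bias["loo", ]), 0)

  expect_error(noise_ceiling_upper(list(a)), ">= 2")
})
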