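test_that("one-vs-rest balancing subsamples negatives to the positive count", {
  labs <- rep(nf_categories, times = c(800, 800, 800, 800, 800))
  b <- balance_one_vs_rest(labs, "face", seed = 1)
  expect_equal(length(b$pos), 800)
  expect_equal(length(b$neg), 800)
  expect_true(all(labs[b$pos] == "face"))
  expect_true(all(labs[b$neg] != "face"))
  expect_equal(anyDuplicated(b$neg), 0)

  labs2 <- rep(nf_categories, times = c(160, 160, 160, 160, 160))
  b2 <- balance_one_vs_rest(labs2, "chair", seed = 1)
  expect_equal(length(b2$neg), 160)

  ## equal classes: negatives returned unchanged
  labs3 <- rep(c("face", "animal"), each = 10)
  b3 <- balance_one_vs_rest(labs3, "face", seed = 1)
  expect_equal(sort(b3$neg), 11:20)

  expect_error(balance_one_vs_rest(c("face", "face", "animal"), "face"),
               "fewer negative")
})

test_that("pseudo-trial partition sizes and means follow the contract", {
  x <- matrix(rnorm(800 * 3), 800, 3)
  p <- make_pseudotrials(x, 150, seed = 2)
  sizes <- attr(p, "set_sizes")
  expect_equal(sort(unique(sizes)), c(5, 6))
  expect_equal(sum(sizes == 5), 100)
  expect_equal(sum(sizes == 6), 50)
  expect_equal(sum(sizes), 800)

  ## n_sets = trial count: identity up to ordering
  x2 <- matrix(rnorm(20), 10, 2)
  p2 <- make_pseudotrials(x2, 10, seed = 3)
  expect_equal(sort(p2[, 1]), sort(x2[, 1]))

  ## constant trials average to the constant (3D path)
  x3 <- array(7, dim = c(9, 2, 4))
  p3 <- make_pseudotrials(x3, 4, seed = 4)
  expect_true(all(p3 == 7))

  expect_error(make_pseudotrials(x2, 11), "exceeds")
})

test_that("noise normalization inverts a known diagonal covariance", {
  tr <- matrix(rnorm(40), 20, 2)
  nn <- noise_normalize(tr, sigma = diag(c(1, 4)))
  expect_equal(nn$W, diag(c(1, 0.5)), tolerance = 1e-10)
  expect_equal(nn$condition_number, 4, tolerance = 1e-10)

  ## white-noise input: estimated transform is near identity
  set.seed(9)
  big <- array(rnorm(400 * 6 * 3), dim = c(400, 6, 3))
  cl <- rep(c("a", "b"), each = 200)
  nn2 <- noise_normalize(big, classes = cl, shrinkage = 0.2)
  expect_lt(max(abs(nn2$W - diag(6))), 0.15)

  ## whitening with the identity covariance leaves fold predictions unchanged
  set.seed(10)
  xtr <- matrix(rnorm(24), 12, 2)
  y <- factor(rep(c("target", "rest"), 6), levels = c("target", "rest"))
  xte <- matrix(rnorm(10), 5, 2)
  nn3 <- noise_normalize(xtr, xte, sigma = diag(2))
  expect_identical(
    neurofusion:::svm_predict(xtr, y, xte, 1),
    neurofusion:::svm_predict(nn3$train, y, nn3$test, 1)
  )

  expect_error(noise_normalize(matrix(1, 1, 3)), "estimable")
})

test_that("whitened training covariance has reduced off-diagonal structure", {
  set.seed(11)
  sig <- matrix(0.8, 4, 4); diag(sig) <- 1
  x <- matrix(rnorm(600 * 4), 600, 4) %*% chol(sig)
  nn <- noise_normalize(x, shrinkage = 0.05)
  before <- max(abs(cov(x)[upper.tri(sig)]))
  after <- max(abs(cov(nn$train)[upper.tri(sig)]))
  expect_lt(after, before / 4)
})

test_that("decoding a linearly separable toy is perfect; chance on pure noise", {
  ## hand toy: two categories separated along channel 1 at every timepoint
  des <- data.frame(condition_id = rep(1:2, each = 8),
                    category = rep(c("face", "animal"), each = 8),
                    identity = 1, variation = "v1",
                    repetition = rep(1:8, 2))
  set.seed(12)
  dat <- array(rnorm(16 * 2 * 3, sd = 0.05), dim = c(16, 2, 3))
  dat[1:8, 1, ] <- dat[1:8, 1, ] + 2
  ch <- data.frame(name = c("c1", "c2"), region = NA)
  ep <- epoched_recording(dat, 0:2, 1000, ch, des, "s", "EEG")
  dp <- decoding_params(n_pseudotrials = 4, n_repeats = 1, whiten = FALSE,
                        seed = 5)
  res <- decode_timecourse(ep, decode_scheme("category_selectivity"), dp)
  expect_true(all(res$accuracy == 1))
  expect_equal(dim(res$accuracy), c(1, 2, 3))
})

test_that("ECoG range features follow the max-minus-min contract", {
  des <- data.frame(condition_id = 1, category = "face", identity = 1,
                    variation = "v1", repetition = 1)
  tm <- 0:349
  ## constant signal -> all features zero
  cst <- epoched_recording(array(5, dim = c(1, 2, 350)), tm, 1000,
                           data.frame(name = c("e1", "e2"), region = NA),
                           des, "s", "ECoG")
  fv <- ecog_feature_vector(cst, window = c(50, 300), bin_ms = 25)
  expect_equal(ncol(fv$features), 20)  # 10 bins x 2 electrodes
  expect_true(all(fv$features == 0))
  expect_equal(fv$bin_starts_ms, seq(50, 275, by = 25))

  ## linear ramp of slope s per ms: range over one 25 ms bin = 24 s
  s <- 0.3
  ramp <- epoched_recording(array(rep(s * tm, each = 1), dim = c(1, 1, 350)),
                            tm, 1000, data.frame(name = "e1", region = NA),
                            des, "s", "ECoG")
  fr <- ecog_feature_vector(ramp, window = c(50, 300), bin_ms = 25)
  expect_equal(as.vector(fr$features), rep(s * 24, 10), tolerance = 1e-12)

  expect_error(ecog_feature_vector(cst, window = c(50, 310), bin_ms = 25),
               "multiple")
  expect_error(ecog_feature_vector(cst, electrodes = "missing"), "unknown")
})

test_that("static decoding respects the run and trial fold structures", {
  ## leave-one-run-out training pools: 175 positives per fold under the
  ## 5 x 5 x 5 design with 7 training repetitions
  d <- make_design(5, 5, 5, n_repetitions = 8, n_runs = 8)
  for (ro in c(1, 5)) {
    ## 5 identities x 5 variations x 7 training runs = 175 positives,
    ## balanced against 175 of the 700 other-category training rows
    expect_equal(sum(d$run != ro & d$category == "face"), 175)
    expect_equal(sum(d$run != ro & d$category != "face"), 700)
  }
  ## invariance pools: 40 positives (5 identities x 1 variation x 8 reps)
  expect_equal(sum(d$category == "face" & d$variation == "v1"), 40)
  expect_equal(sum(d$category != "face" & d$variation == "v1"), 160)

  ## separable static toy: perfect leave-one-run-out decoding
  des <- make_design(2, 1, 1, n_repetitions = 4, n_runs = 4)
  set.seed(13)
  X <- matrix(rnorm(8 * 3, sd = 0.05), 8, 3)
  X[des$category == "animal", 1] <- X[des$category == "animal", 1] + 3
  ps <- pattern_set(X, des[, c("condition_id", "run")], "O-Inf", "sub-01")
  ps$labels$category <- des$category
  ps$labels$variation <- des$variation
  dp <- decoding_params(n_repeats = 1, whiten = FALSE, seed = 6)
  res <- decode_static(ps, decode_scheme("category_selectivity"), dp, cv = "run")
  expect_true(all(res$accuracy == 1))

  ## single run rejected for leave-one-run-out
  des1 <- make_design(2, 1, 1, n_repetitions = 1, n_runs = 1)
  ps1 <- pattern_set(matrix(rnorm(2 * 3), 2), des1[, c("condition_id", "run")],
                     "O-Inf", "s")
  ps1$labels$category <- des1$category
  ps1$labels$variation <- des1$variation
  expect_error(decode_static(ps1, decode_scheme("category_selectivity"), dp,
                             cv = "run"),
               "at least 2 runs")
})

test_that("invariance schemes train on the reference condition and average tests", {
  sch <- decode_scheme("rotation_invariance")
  expect_equal(sch$train_variations, "v1")
  expect_equal(sch$test_variations, c("v2", "v3"))
  expect_equal(decode_scheme("scale_invariance")$test_variations, c("v4", "v5"))

  ## cross-decoding on fully invariant separable data is perfect
  des <- make_design(2, 1, 5, n_repetitions = 4)
  p <- generator_params(n_participants = 1, n_channels = 6, sfreq = 50,
                        epoch_window = c(0, 200), n_repetitions = 4,
                        rho_inv = 1, noise_sd = 0.05,
                        category_amplitudes = c(face = 2, animal = 2),
                        seed = 8)
  eeg <- simulate_eeg(p, des)[[1]]
  dp <- decoding_params(n_repeats = 1, whiten = FALSE, seed = 9)
  res <- decode_timecourse(eeg, sch, dp)
  peak_idx <- which.min(abs(eeg$time_ms - 150))
  expect_true(all(res$accuracy[, , peak_idx] == 1))
  ## a scheme whose test variations are absent is rejected
  des_v1 <- make_design(2, 1, 1, n_repetitions = 4)
  eeg_v1 <- simulate_eeg(p, des_v1)[[1]]
  expect_error(decode_timecourse(eeg_v1, sch, dp), "absent")
})

test_that("accuracies are bounded and aggregation shapes are consistent", {
  des <- tiny_design(n_variations = 1)
  p <- tiny_params(n_participants = 2)
  eeg <- simulate_eeg(p, des)
  dp <- decoding_params(n_pseudotrials = 2, n_repeats = 1, seed = 10)
  res <- decode_timecourse(eeg, decode_scheme("category_selectivity"), dp)
  expect_true(all(res$accuracy >= 0 & res$accuracy <= 1))
  expect_equal(length(group_accuracy(res)), length(eeg[[1]]$time_ms))
  expect_equal(dim(category_accuracy(res)), c(length(eeg[[1]]$time_ms), 5))
  expect_equal(dim(participant_accuracy(res)), c(2, length(eeg[[1]]$time_ms)))
})
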