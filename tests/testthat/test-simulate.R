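test_that("identical seeds give bit-identical synthetic data", {
  des <- tiny_design()
  p <- tiny_params(n_participants = 2)
  expect_identical(simulate_eeg(p, des), simulate_eeg(p, des))
  expect_identical(simulate_ecog(p, des), simulate_ecog(p, des))
  desf <- make_design(5, 2, 5, n_repetitions = 2, n_runs = 2)
  pf <- tiny_params(n_voxels = 10, n_runs = 2)
  expect_identical(simulate_fmri(pf, desf), simulate_fmri(pf, desf))
  ## different seed changes the data
  p2 <- tiny_params(seed = 43)
  expect_false(identical(simulate_eeg(p, des)[[1]]$data,
                         simulate_eeg(p2, des)[[1]]$data))
})

test_that("zero category amplitude yields pure noise", {
  des <- tiny_design()
  amps0 <- setNames(rep(0, 5), nf_categories)
  p <- tiny_params(category_amplitudes = amps0, temporal_smoothing = 0,
                   channel_corr_scale = 0)
  eeg <- simulate_eeg(p, des)[[1]]
  expect_lt(abs(mean(eeg$data)), 0.02)
  expect_lt(abs(sd(eeg$data) - p$noise_sd), 0.02)
})

test_that("pre-onset samples carry noise only and the envelope peaks on time", {
  des <- tiny_design(n_variations = 1)
  p <- generator_params(n_participants = 1, n_channels = 8, sfreq = 200,
                        epoch_window = c(-100, 300), n_repetitions = 4,
                        signal_onset = 80, signal_peak = 150,
                        noise_sd = 1e-6, seed = 7)
  eeg <- simulate_eeg(p, des)[[1]]
  pre <- eeg$data[, , eeg$time_ms < 80]
  expect_lt(max(abs(pre)), 1e-4)
  ## signal power peaks at the envelope peak
  pow <- apply(eeg$data^2, 3, mean)
  expect_equal(eeg$time_ms[which.max(pow)], 150)
})

test_that("full invariance makes patterns identical across viewing conditions", {
  des <- make_design(5, 1, 5, n_repetitions = 2)
  p <- generator_params(n_participants = 1, n_channels = 8, sfreq = 50,
                        epoch_window = c(0, 200), n_repetitions = 2,
                        rho_inv = 1, noise_sd = 1e-9, seed = 3)
  eeg <- simulate_eeg(p, des)[[1]]
  lab <- eeg$labels
  v1 <- which(lab$category == "face" & lab$variation == "v1")[1]
  v3 <- which(lab$category == "face" & lab$variation == "v3")[1]
  expect_equal(eeg$data[v1, , ], eeg$data[v3, , ], tolerance = 1e-6)
  ## at rho_inv = 0 the viewing conditions have distinct patterns
  p0 <- generator_params(n_participants = 1, n_channels = 8, sfreq = 50,
                         epoch_window = c(0, 200), n_repetitions = 2,
                         rho_inv = 0, noise_sd = 1e-9, seed = 3)
  eeg0 <- simulate_eeg(p0, des)[[1]]
  expect_gt(max(abs(eeg0$data[v1, , ] - eeg0$data[v3, , ])), 1e-3)
})

test_that("ECoG regional latency offsets order the band-power peaks", {
  des <- tiny_design(n_repetitions = 4)
  offs <- c("O-Inf" = 0, "T-MLing" = 0, "T-LFus" = 0, "T-MTPhip" = 0,
            "T-IT" = 0, "T-Pole" = 100)
  p <- generator_params(n_participants = 1, n_channels = 8, sfreq = 500,
                        epoch_window = c(0, 400), n_repetitions = 4,
                        region_latency_offsets = offs,
                        ecog_electrodes = c("O-Inf" = 6, "T-Pole" = 6),
                        noise_sd = 0.05, seed = 5)
  ecog <- simulate_ecog(p, des)
  ## oracle: peak of 25 ms band power per region
  bp <- function(region) {
    idx <- which(ecog$channels$region == region)
    pow <- apply(ecog$data[, idx, , drop = FALSE]^2, 3, mean)
    b <- bin_timecourse(pow, ecog$time_ms, 25)
    b$time_ms[which.max(b$values)]
  }
  expect_lt(abs(bp("O-Inf") - p$signal_peak), 25)
  expect_gt(bp("T-Pole"), bp("O-Inf") + 50)
})

test_that("non-selective ECoG electrodes are noise only", {
  des <- tiny_design()
  p <- tiny_params(selective_fraction = 0, sfreq = 500,
                   epoch_window = c(0, 300),
                   ecog_electrodes = c("O-Inf" = 6, "T-IT" = 4))
  ecog <- simulate_ecog(p, des)
  cm <- condition_means(ecog)
  ## condition means are all noise-scale (no category structure)
  expect_lt(max(abs(cm)), 6 * p$noise_sd / sqrt(4))
})

test_that("ECoG rejects unknown region labels", {
  des <- tiny_design()
  expect_error(tiny_params(ecog_electrodes = c(Occ = 4)), "region")
  p <- tiny_params()
  p$region_latency_offsets <- c(bogus = 10)
  expect_error(simulate_ecog(p, des), "region")
})

test_that("fMRI pattern sets have one beta row per condition and run", {
  desf <- make_design(5, 5, 5, n_repetitions = 8, n_runs = 8)
  p <- generator_params(n_participants = 1, n_voxels = 5, n_runs = 8, seed = 2)
  fm <- simulate_fmri(p, desf)
  ps <- fm[[1]][["O-Inf"]]
  expect_equal(nrow(ps$betas), 1000)  # 125 x 8
  expect_true(all(table(ps$labels$condition_id) == 8))
  expect_named(fm[[1]], nf_rois)
})

test_that("a zero-SNR ROI contains no category signal", {
  desf <- make_design(5, 2, 5, n_repetitions = 2, n_runs = 2)
  snr <- c("O-Inf" = 1, "T-LFus" = 1, "T-MLing" = 1, "T-MTPhip" = 1,
           "T-IT" = 1, "T-Pole" = 0)
  p <- generator_params(n_participants = 1, n_voxels = 12, n_runs = 2,
                        roi_snr = snr, seed = 4)
  fm <- simulate_fmri(p, desf)
  cm0 <- condition_means(fm[[1]][["T-Pole"]]$betas, fm[[1]][["T-Pole"]]$labels)
  cm1 <- condition_means(fm[[1]][["O-Inf"]]$betas, fm[[1]][["O-Inf"]]$labels)
  ## signal variance across conditions: present at SNR 1, absent at SNR 0
  expect_gt(var(rowMeans(cm1^2)), var(rowMeans(cm0^2)))
  p$roi_snr <- snr[1:3]
  expect_error(simulate_fmri(p, desf), "missing ROIs")
})

test_that("generator parameter validation catches contract violations", {
  expect_error(tiny_params(rho_inv = 1.5), "rho_inv")
  expect_error(tiny_params(noise_sd = 0), "noise_sd")
  expect_error(generator_params(signal_onset = 150, signal_peak = 80), "precede")
  expect_error(generator_params(epoch_window = c(200, 600)), "envelope")
  expect_error(tiny_params(temporal_smoothing = 1), "temporal_smoothing")
})

test_that("epoched_recording enforces axis and label consistency", {
  dat <- array(0, dim = c(2, 3, 4))
  ch <- data.frame(name = c("a", "b", "c"), region = NA)
  lab <- data.frame(condition_id = 1:2)
  expect_error(epoched_recording(dat, c(0, 1, 2), 1000, ch, lab, "s", "EEG"),
               "time axis")
  expect_error(epoched_recording(dat, c(0, 1, 2, 3), 500, ch, lab, "s", "EEG"),
               "uniform")
  expect_error(epoched_recording(dat, c(0, 1, 2, 3), 1000, ch,
                                 lab[1, , drop = FALSE], "s", "EEG"),
               "labels")
})
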