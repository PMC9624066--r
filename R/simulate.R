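#' Parameters for the synthetic multimodal generator
#'
#' Bundles and validates every knob of the synthetic EEG/ECoG/fMRI generator.
#' Defaults reproduce the study design the package emulates: 21 participants,
#' 64 EEG channels sampled at 1 kHz, epochs from -100 to +600 ms, 32
#' repetitions per condition, and a category-selective response rising at
#' 80 ms and peaking at 150 ms after stimulus onset.
#'
#' The category response of every simulated trial is a spatial activation
#' pattern modulated by a Gaussian temporal envelope.  The pattern for a
#' (category, variation) cell mixes a variation-shared component with a
#' variation-specific component with weight `rho_inv`: at `rho_inv = 1`
#' representations are fully tolerant to viewing conditions (cross-decoding
#' equals within-decoding), at `rho_inv = 0` each viewing condition has an
#' unrelated pattern.  The envelope standard deviation is derived from
#' (`signal_onset`, `signal_peak`) so that the envelope first exceeds 5% of
#' its peak exactly at `signal_onset`; below that 5% floor the envelope is
#' exactly zero, so pre-onset samples carry noise only.
#'
#' @param n_participants Number of simulated participants.
#' @param n_channels Number of EEG channels.
#' @param sfreq Sampling frequency in Hz.
#' @param epoch_window Epoch limits in ms relative to stimulus onset,
#'   `c(tmin, tmax)`.
#' @param n_repetitions Repetitions per condition.
#' @param signal_onset,signal_peak Envelope onset and peak, in ms.  The
#'   envelope SD is `(signal_peak - signal_onset) / sqrt(2 * log(20))`.
#' @param category_amplitudes Named numeric vector of per-category response
#'   amplitudes, in multiples of the noise SD.  The default gives the face
#'   category the largest response, matching the robust face advantage seen
#'   in visual decoding studies.
#' @param rho_inv Invariance mixing weight in \[0, 1\].
#' @param identity_jitter Weight of the variation-independent
#'   identity-specific pattern component.  Individual objects evoke partly
#'   distinct patterns; this is what gives the 125-condition RDMs their
#'   within-category structure.  It does not depend on the viewing
#'   condition, so the `rho_inv = 1` full-invariance contract is preserved.
#' @param noise_sd Noise standard deviation (> 0).
#' @param channel_corr_scale Spatial length scale (in channel-index units) of
#'   the exponential inter-channel noise correlation; 0 gives independent
#'   channels.
#' @param temporal_smoothing AR(1) coefficient of the temporal noise
#'   autocorrelation, in \[0, 1).
#' @param region_latency_offsets Named vector (over [nf_rois]) of per-region
#'   latency offsets in ms, applied to the ECoG envelope.  The default
#'   ordering (occipital earliest, temporal pole latest) mirrors the posterior
#'   to anterior sweep of visual responses.
#' @param roi_snr Named vector (over [nf_rois]) of positive fMRI pattern
#'   scales; the default grades SNR down from occipital to temporal-pole
#'   cortex, emulating the well-known fMRI signal loss near the ear canals.
#' @param ecog_electrodes Named integer vector: electrodes per region in the
#'   pooled ECoG super-subject (default non-uniform, occipital-heavy).
#' @param ecog_carrier_hz Frequency (Hz) of the rectified carrier that
#'   modulates the ECoG response within the envelope.  Intracranial field
#'   potential category responses are broadband power modulations, so the
#'   ECoG signal rides on `|sin|` of this carrier; this is what makes the
#'   within-bin signal range (max - min) informative, as it is for real
#'   field potentials.  Choose a sampling rate of at least ~8x the carrier.
#' @param ecog_amplitude_scale Multiplier on the category amplitudes for
#'   ECoG electrodes.  Visually selective intracranial electrodes carry far
#'   larger single-trial effects than scalp sensors; the default puts
#'   super-subject range-feature decoding in the 0.6-0.9 peak-accuracy band
#'   typical of intracranial reports.
#' @param selective_fraction Fraction of ECoG electrodes per region that carry
#'   signal; the rest are noise-only.
#' @param n_voxels Voxels per simulated fMRI region of interest.
#' @param n_runs fMRI runs per participant.
#' @param seed Master integer seed.  Participant `k` draws from its own
#'   stream seeded with `(seed * 1000 + k) mod 2147483629`, keeping
#'   participants independent yet individually reproducible.
#'
#' @return A validated list of class `generator_params`.
#' @export
generator_params <- function(n_participants = 21,
                             n_channels = 64,
                             sfreq = 1000,
                             epoch_window = c(-100, 600),
                             n_repetitions = 32,
                             signal_onset = 80,
                             signal_peak = 150,
                             category_amplitudes = c(animal = 0.9, chair = 0.7,
                                                     face = 1.4, fruit = 0.6,
                                                     vehicle = 1.0),
                             rho_inv = 0.5,
                             identity_jitter = 0.3,
                             noise_sd = 1,
                             channel_corr_scale = 3,
                             temporal_smoothing = 0.3,
                             region_latency_offsets = c("O-Inf" = 0, "T-MLing" = 5,
                                                        "T-LFus" = 20, "T-MTPhip" = 60,
                                                        "T-IT" = 80, "T-Pole" = 100),
                             roi_snr = c("O-Inf" = 1, "T-LFus" = 0.8,
                                         "T-MLing" = 0.7, "T-MTPhip" = 0.4,
                                         "T-IT" = 0.3, "T-Pole" = 0.15),
                             ecog_electrodes = c("O-Inf" = 30, "T-LFus" = 13,
                                                 "T-MLing" = 8, "T-MTPhip" = 9,
                                                 "T-IT" = 6, "T-Pole" = 5),
                             ecog_carrier_hz = 60,
                             ecog_amplitude_scale = 4,
                             selective_fraction = 1,
                             n_voxels = 50,
                             n_runs = 8,
                             seed = 1L) {
  stopifnot(n_participants >= 1, n_channels >= 2, sfreq > 0, n_repetitions >= 1)
  if (length(epoch_window) != 2 || epoch_window[1] >= epoch_window[2]) {
    stop("epoch_window must be c(tmin, tmax) with tmin < tmax")
  }
  if (rho_inv < 0 || rho_inv > 1) stop("rho_inv must lie in [0, 1]")
  if (identity_jitter < 0) stop("identity_jitter must be non-negative")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  if (temporal_smoothing < 0 || temporal_smoothing >= 1) {
    stop("temporal_smoothing must lie in [0, 1)")
  }
  if (signal_onset >= signal_peak) stop("signal_onset must precede signal_peak")
  if (signal_onset < epoch_window[1] || signal_peak > epoch_window[2]) {
    stop("epoch_window must contain the envelope support (signal_onset..signal_peak)")
  }
  if (is.null(names(category_amplitudes)) ||
      !all(names(category_amplitudes) %in% nf_categories)) {
    stop("category_amplitudes must be named with categories from nf_categories")
  }
  if (!all(names(region_latency_offsets) %in% nf_rois)) {
    stop("unknown region label in region_latency_offsets; use nf_rois")
  }
  if (!all(names(ecog_electrodes) %in% nf_rois)) {
    stop("unknown region label in ecog_electrodes; use nf_rois")
  }
  if (any(roi_snr < 0)) stop("roi_snr entries must be non-negative")
  if (selective_fraction < 0 || selective_fraction > 1) {
    stop("selective_fraction must lie in [0, 1]")
  }
  p <- list(n_participants = as.integer(n_participants),
            n_channels = as.integer(n_channels), sfreq = sfreq,
            epoch_window = epoch_window, n_repetitions = as.integer(n_repetitions),
            signal_onset = signal_onset, signal_peak = signal_peak,
            category_amplitudes = category_amplitudes, rho_inv = rho_inv,
            identity_jitter = identity_jitter, noise_sd = noise_sd, channel_corr_scale = channel_corr_scale,
            temporal_smoothing = temporal_smoothing,
            region_latency_offsets = region_latency_offsets,
            roi_snr = roi_snr, ecog_electrodes = ecog_electrodes,
            ecog_carrier_hz = ecog_carrier_hz,
            ecog_amplitude_scale = ecog_amplitude_scale,
            selective_fraction = selective_fraction,
            n_voxels = as.integer(n_voxels), n_runs = as.integer(n_runs),
            seed = as.integer(seed))
  class(p) <- "generator_params"
  p
}

## Envelope-onset rule: the Gaussian first exceeds 5% of its peak at
## signal_onset, i.e. sd = (peak - onset) / sqrt(2 log 20).
envelope_sd <- function(params) {
  (params$signal_peak - params$signal_onset) / sqrt(2 * log(20))
}

#' Gaussian response envelope with a hard 5% onset
#'
#' @param time_ms Time axis in ms.
#' @param params A [generator_params()] object.
#' @param offset_ms Latency offset added to both onset and peak (ECoG regions).
#' @return Numeric vector in \[0, 1\]; exactly 0 before onset.
#' @keywords internal
signal_envelope <- function(time_ms, params, offset_ms = 0) {
  sd <- envelope_sd(params)
  g <- exp(-(time_ms - (params$signal_peak + offset_ms))^2 / (2 * sd^2))
  g[g < 0.05] <- 0
  g
}

participant_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1000 + k) %% 2147483629)
}

## Spatially correlated (exponential decay over channel index distance),
## temporally AR(1)-smoothed Gaussian noise for one trial block.
## Returns an array [n_trials x n_channels x n_time].
make_noise <- function(n_trials, n_channels, n_time, params, chol_factor = NULL) {
  if (is.null(chol_factor)) chol_factor <- noise_chol(n_channels, params$channel_corr_scale)
  phi <- params$temporal_smoothing
  z <- matrix(stats::rnorm(n_time * n_channels * n_trials), nrow = n_time)
  if (phi > 0) {
    ## AR(1) over time, unit marginal variance, all trial/channel columns at once
    z <- stats::filter(z * sqrt(1 - phi^2), phi, method = "recursive")
  }
  ## [time x channel x trial] -> spatial mixing over the channel dimension
  z <- aperm(array(as.numeric(z), dim = c(n_time, n_channels, n_trials)),
             c(2, 1, 3))
  dim(z) <- c(n_channels, n_time * n_trials)
  z <- params$noise_sd * (chol_factor %*% z)
  dim(z) <- c(n_channels, n_time, n_trials)
  aperm(z, c(3, 1, 2))
}

noise_chol <- function(n_channels, scale) {
  if (scale <= 0) return(diag(n_channels))
  d <- abs(outer(seq_len(n_channels), seq_len(n_channels), "-"))
  sigma <- exp(-d / scale)
  t(chol(sigma))
}

unit_norm <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) v else v / n
}

## Spatial patterns per (category, identity, variation): rho_inv-weighted
## mix of a category-shared and a variation-specific random direction, plus
## a variation-INDEPENDENT identity component (weight identity_jitter), all
## unit-normed so amplitude is comparable across rho_inv, then scaled by the
## category amplitude.  Because the identity component does not depend on
## the viewing condition, rho_inv = 1 still makes patterns identical across
## variations.  Returns patterns[[category]][[variation]] = matrix
## [identity x feature]; look rows up with match(identity, attr "identities").
make_patterns <- function(n_features, design, params) {
  cats <- unique(design$category)
  vars <- unique(design$variation)
  ids <- sort(unique(design$identity))
  amps <- params$category_amplitudes
  jit <- params$identity_jitter
  patterns <- list()
  for (ct in cats) {
    shared <- unit_norm(stats::rnorm(n_features))
    idcomp <- t(vapply(ids, function(i) unit_norm(stats::rnorm(n_features)),
                       numeric(n_features)))
    amp <- if (ct %in% names(amps)) amps[[ct]] else 0
    patterns[[ct]] <- list()
    for (v in vars) {
      specific <- unit_norm(stats::rnorm(n_features))
      mix <- unit_norm(params$rho_inv * shared + (1 - params$rho_inv) * specific)
      mat <- t(vapply(seq_along(ids), function(k) {
        amp * unit_norm(mix + jit * idcomp[k, ])
      }, numeric(n_features)))
      attr(mat, "identities") <- ids
      patterns[[ct]][[v]] <- mat
    }
  }
  patterns
}

pattern_row <- function(patterns, category, variation, identity) {
  mat <- patterns[[category]][[variation]]
  mat[match(identity, attr(mat, "identities")), ]
}

#' Construct an epoched recording
#'
#' @param data Numeric array `[trial x channel x timepoint]`.
#' @param time_ms Uniform time axis in ms (length = 3rd dimension of `data`).
#' @param sfreq Sampling frequency in Hz.
#' @param channels `data.frame` with columns `name` and `region` (region may
#'   be `NA` for unlabeled sensors).
#' @param labels `condition_table` rows, one per trial.
#' @param participant_id Participant token.
#' @param modality `"EEG"` or `"ECoG"`.
#' @return An object of class `epoched_recording`.
#' @export
epoched_recording <- function(data, time_ms, sfreq, channels, labels,
                              participant_id, modality = c("EEG", "ECoG")) {
  modality <- match.arg(modality)
  stopifnot(length(dim(data)) == 3)
  if (length(time_ms) != dim(data)[3]) {
    stop("time axis length must equal the third dimension of data")
  }
  step <- diff(time_ms)
  if (length(step) > 0 &&
      (any(step <= 0) || any(abs(step - 1000 / sfreq) > 1e-6))) {
    stop("time axis must be strictly increasing with uniform step 1000/sfreq")
  }
  if (nrow(labels) != dim(data)[1]) {
    stop("labels must have one row per trial")
  }
  if (nrow(channels) != dim(data)[2]) {
    stop("channels must have one row per channel")
  }
  structure(list(data = data, time_ms = time_ms, sfreq = sfreq,
                 channels = channels, labels = labels,
                 participant_id = participant_id, modality = modality),
            class = "epoched_recording")
}

#' @export
print.epoched_recording <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoched_recording> %s %s: %d trials x %d channels x %d timepoints (%g..%g ms @ %g Hz)\n",
              x$modality, x$participant_id, d[1], d[2], d[3],
              min(x$time_ms), max(x$time_ms), x$sfreq))
  invisible(x)
}

epoch_time_axis <- function(params) {
  seq(params$epoch_window[1], params$epoch_window[2], by = 1000 / params$sfreq)
}

#' Simulate EEG epochs for all participants
#'
#' Each trial is `amplitude x spatial pattern x temporal envelope` plus
#' spatially correlated, temporally smoothed Gaussian noise (see
#' [generator_params()]).  With all category amplitudes zero the output is
#' pure noise and downstream decoding is calibrated at chance.
#'
#' @param params A [generator_params()] object.
#' @param design A [make_design()] condition table (trials of one participant).
#' @return List of [epoched_recording()] objects, one per participant.
#' @export
simulate_eeg <- function(params, design) {
  stopifnot(inherits(params, "generator_params"))
  time_ms <- epoch_time_axis(params)
  chol_factor <- noise_chol(params$n_channels, params$channel_corr_scale)
  channels <- data.frame(name = sprintf("EEG%03d", seq_len(params$n_channels)),
                         region = NA_character_, stringsAsFactors = FALSE)
  lapply(seq_len(params$n_participants), function(k) {
    set.seed(participant_seed(params$seed, k))
    patterns <- make_patterns(params$n_channels, design, params)
    env <- signal_envelope(time_ms, params)
    data <- make_noise(nrow(design), params$n_channels, length(time_ms),
                       params, chol_factor)
    for (tr in seq_len(nrow(design))) {
      p <- pattern_row(patterns, design$category[tr], design$variation[tr],
                       design$identity[tr])
      data[tr, , ] <- data[tr, , ] + outer(p, env)
    }
    epoched_recording(data, time_ms, params$sfreq, channels, design,
                      participant_id = sprintf("sub-%02d", k), modality = "EEG")
  })
}

#' Simulate a pooled ECoG super-subject
#'
#' Electrodes are generated already pooled across pseudo-patients, with
#' region labels from [nf_rois]; intracranial coverage is sparse per patient,
#' so pooling mirrors common practice.  Each region's response envelope is
#' shifted by its latency offset, and only a `selective_fraction` of its
#' electrodes carry signal; the rest are noise-only.  Noise is correlated
#' within a region but independent across regions (electrodes of different
#' patients share no noise source).
#'
#' @inheritParams simulate_eeg
#' @return A single [epoched_recording()] with `modality = "ECoG"`.
#' @export
simulate_ecog <- function(params, design) {
  stopifnot(inherits(params, "generator_params"))
  regions <- names(params$ecog_electrodes)
  if (!all(names(params$region_latency_offsets) %in% nf_rois)) {
    stop("unknown region label in region_latency_offsets")
  }
  missing_off <- setdiff(regions, names(params$region_latency_offsets))
  if (length(missing_off)) {
    stop("region_latency_offsets missing regions: ",
         paste(missing_off, collapse = ", "))
  }
  time_ms <- epoch_time_axis(params)
  set.seed(participant_seed(params$seed, 0L))
  n_elec <- sum(params$ecog_electrodes)
  channels <- data.frame(
    name = sprintf("ECOG%03d", seq_len(n_elec)),
    region = rep(regions, times = params$ecog_electrodes),
    pseudo_patient = sprintf("pat-%02d", (seq_len(n_elec) - 1L) %% 11L + 1L),
    stringsAsFactors = FALSE
  )
  data <- array(0, dim = c(nrow(design), n_elec, length(time_ms)))
  for (r in regions) {
    idx <- which(channels$region == r)
    n_r <- length(idx)
    n_sel <- round(params$selective_fraction * n_r)
    sel <- sort(sample(idx, n_sel))
    patterns <- make_patterns(n_r, design, params)
    off <- params$region_latency_offsets[[r]]
    env <- signal_envelope(time_ms, params, offset_ms = off) *
      abs(sin(2 * pi * params$ecog_carrier_hz *
                (time_ms - params$signal_onset - off) / 1000))
    chol_r <- noise_chol(n_r, params$channel_corr_scale)
    block <- make_noise(nrow(design), n_r, length(time_ms), params, chol_r)
    for (tr in seq_len(nrow(design))) {
      p <- params$ecog_amplitude_scale *
        pattern_row(patterns, design$category[tr], design$variation[tr],
                    design$identity[tr])
      p[!(idx %in% sel)] <- 0
      block[tr, , ] <- block[tr, , ] + outer(p, env)
    }
    data[, idx, ] <- block
  }
  epoched_recording(data, time_ms, params$sfreq, channels, design,
                    participant_id = "super-subject", modality = "ECoG")
}

#' Construct an fMRI-style pattern set
#'
#' @param betas Numeric matrix `[condition-row x voxel]`.
#' @param labels `data.frame` with columns `condition_id` and (optionally)
#'   `run`, one row per row of `betas`.
#' @param roi Region-of-interest label (one of [nf_rois]).
#' @param participant_id Participant token.
#' @return An object of class `pattern_set`.
#' @export
pattern_set <- function(betas, labels, roi, participant_id) {
  stopifnot(is.matrix(betas), nrow(betas) == nrow(labels))
  if (!roi %in% nf_rois) stop("unknown ROI label: ", roi)
  key <- if ("run" %in% names(labels)) {
    paste(labels$condition_id, labels$run)
  } else {
    as.character(labels$condition_id)
  }
  if (anyDuplicated(key)) stop("duplicate (condition, run) rows in pattern set")
  structure(list(betas = betas, labels = labels, roi = roi,
                 participant_id = participant_id),
            class = "pattern_set")
}

#' Simulate fMRI beta patterns per participant, ROI and run
#'
#' Per-ROI (category x variation) voxel patterns are scaled by `roi_snr` and
#' the category amplitude, then corrupted with independent Gaussian voxel
#' noise; each run contributes one beta row per condition.
#'
#' @inheritParams simulate_eeg
#' @param design Condition table with a `run` column covering all conditions
#'   in every run (e.g. `make_design(5, 5, 5, n_repetitions = 8, n_runs = 8)`).
#' @return Nested list: `result[[participant]][[roi]]` is a [pattern_set()].
#' @export
simulate_fmri <- function(params, design) {
  stopifnot(inherits(params, "generator_params"))
  if (!"run" %in% names(design)) stop("fMRI design requires a run column")
  rois <- nf_rois
  missing_snr <- setdiff(rois, names(params$roi_snr))
  if (length(missing_snr)) {
    stop("roi_snr missing ROIs: ", paste(missing_snr, collapse = ", "))
  }
  lapply(seq_len(params$n_participants), function(k) {
    set.seed(participant_seed(params$seed, k))
    out <- lapply(rois, function(r) {
      patterns <- make_patterns(params$n_voxels, design, params)
      snr <- params$roi_snr[[r]]
      betas <- matrix(stats::rnorm(nrow(design) * params$n_voxels,
                                   sd = params$noise_sd),
                      nrow = nrow(design))
      for (tr in seq_len(nrow(design))) {
        p <- pattern_row(patterns, design$category[tr], design$variation[tr],
                         design$identity[tr])
        betas[tr, ] <- betas[tr, ] + snr * p
      }
      pattern_set(betas, design[, c("condition_id", "run")], roi = r,
                  participant_id = sprintf("sub-%02d", k))
    })
    names(out) <- rois
    out
  })
}
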