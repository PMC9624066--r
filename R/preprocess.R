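#' Construct a continuous multichannel recording
#'
#' @param data Numeric matrix `[channel x sample]`.
#' @param sfreq Sampling frequency in Hz (> 0).
#' @param channels Character vector of channel names.
#' @param events `data.frame` with columns `sample` (1-based sample index of
#'   stimulus onset) and `condition_id`.
#' @return An object of class `continuous_recording`.
#' @export
continuous_recording <- function(data, sfreq, channels = NULL, events = NULL) {
  stopifnot(is.matrix(data), sfreq > 0)
  if (is.null(channels)) channels <- sprintf("CH%03d", seq_len(nrow(data)))
  if (length(channels) != nrow(data)) {
    stop("one channel name per data row required")
  }
  if (is.null(events)) {
    events <- data.frame(sample = integer(0), condition_id = integer(0))
  }
  if (nrow(events) > 0 &&
      (any(events$sample < 1) || any(events$sample > ncol(data)))) {
    stop("event sample indices must lie within the recording")
  }
  structure(list(data = data, sfreq = sfreq, channels = channels,
                 events = events),
            class = "continuous_recording")
}

#' Zero-phase FIR low-pass filter
#'
#' Designs a linear-phase (type I) Hamming-windowed FIR low-pass of the given
#' even order and applies it with group-delay compensation: the signal is
#' edge-padded, filtered causally, and the output shifted back by `order/2`
#' samples, so the filter is effectively zero-phase and latency estimates are
#' not biased.  The taps are normalized to unit DC gain.
#'
#' @param x A [continuous_recording()].
#' @param cutoff Cutoff frequency in Hz (must be below Nyquist).
#' @param order Even FIR order (number of taps minus one).
#' @return A filtered `continuous_recording` on the same grid.
#' @export
fir_lowpass <- function(x, cutoff = 40, order = 396) {
  stopifnot(inherits(x, "continuous_recording"))
  nyq <- x$sfreq / 2
  if (cutoff >= nyq) stop("cutoff must be below the Nyquist frequency (", nyq, " Hz)")
  if (order %% 2 != 0) stop("order must be even (linear-phase type I)")
  b <- fir_lowpass_taps(cutoff, order, x$sfreq)
  half <- order / 2
  n <- ncol(x$data)
  filt <- t(apply(x$data, 1, function(row) {
    padded <- c(rep(row[1], order), row, rep(row[n], order))
    y <- stats::filter(padded, b, method = "convolution", sides = 1)
    as.numeric(y[(order + half + 1):(order + half + n)])
  }))
  out <- x
  out$data <- filt
  out
}

#' FIR low-pass tap coefficients (unit DC gain)
#' @keywords internal
fir_lowpass_taps <- function(cutoff, order, sfreq) {
  b <- signal::fir1(order, cutoff / (sfreq / 2), type = "low")
  as.numeric(b) / sum(b)
}

## Smallest rational p/q approximating `ratio` within `tol`, q <= max_q.
rational_ratio <- function(ratio, tol = 1e-9, max_q = 10000) {
  for (q in seq_len(max_q)) {
    p <- round(ratio * q)
    if (p >= 1 && abs(ratio - p / q) < tol) return(c(p = p, q = q))
  }
  stop("resampling factor ", ratio, " has no rational approximation with ",
       "denominator <= ", max_q, " at tolerance ", tol)
}

#' Resample a continuous recording to a new rate
#'
#' Resampling onto the rational grid `p/q = new_sfreq / sfreq` (the ratio is
#' rejected if it is not rational within `1e-9`, so sample grids stay
#' exactly commensurate).  When downsampling, a zero-phase FIR anti-alias
#' low-pass at `0.45 * new_sfreq` is applied first (a no-op after the usual
#' 40 Hz low-pass); the band-limited signal is then reconstructed on the new
#' grid by cubic-spline interpolation, whose error is negligible for
#' frequencies far below Nyquist.  Event sample indices are remapped
#' proportionally.
#'
#' @param x A [continuous_recording()].
#' @param new_sfreq Target rate in Hz.
#' @return A `continuous_recording` at `new_sfreq`, duration preserved within
#'   one sample.
#' @export
resample_recording <- function(x, new_sfreq) {
  stopifnot(inherits(x, "continuous_recording"), new_sfreq > 0)
  if (abs(new_sfreq - x$sfreq) < 1e-12) return(x)
  rational_ratio(new_sfreq / x$sfreq)  # grid-commensurability contract
  if (new_sfreq < x$sfreq) {
    order <- min(396, 2 * ((ncol(x$data) - 1) %/% 4))
    x <- fir_lowpass(x, 0.45 * new_sfreq, order)
  }
  n_old <- ncol(x$data)
  n_new <- floor((n_old - 1) * new_sfreq / x$sfreq) + 1
  t_old <- (seq_len(n_old) - 1) / x$sfreq
  t_new <- (seq_len(n_new) - 1) / new_sfreq
  dat <- t(apply(x$data, 1, function(row) {
    stats::splinefun(t_old, row, method = "fmm")(t_new)
  }))
  events <- x$events
  if (nrow(events) > 0) {
    events$sample <- pmin(pmax(round((events$sample - 1) * new_sfreq / x$sfreq) + 1L, 1L),
                          ncol(dat))
  }
  out <- x
  out$data <- dat
  out$sfreq <- new_sfreq
  out$events <- events
  out
}

#' Re-reference an epoched recording to one channel
#'
#' Subtracts the reference channel's signal from every channel (trial-wise);
#' the reference channel itself becomes identically zero.  Idempotent.
#'
#' @param epochs An [epoched_recording()].
#' @param ref_channel Name of the reference channel.
#' @return Re-referenced `epoched_recording`.
#' @export
rereference <- function(epochs, ref_channel) {
  stopifnot(inherits(epochs, "epoched_recording"))
  ref <- match(ref_channel, epochs$channels$name)
  if (is.na(ref)) stop("reference channel not found: ", ref_channel)
  d <- epochs$data
  ref_sig <- d[, ref, , drop = FALSE]
  for (ch in seq_len(dim(d)[2])) {
    d[, ch, ] <- d[, ch, ] - ref_sig[, 1, ]
  }
  epochs$data <- d
  epochs
}

#' Extract fixed-length epochs around stimulus events
#'
#' Slices `[tmin, tmax]` ms around every event, closed at both ends on the
#' sample grid; 0 ms is the event sample itself.  No baseline correction is
#' applied anywhere in the chain.
#'
#' @param x A [continuous_recording()] with events.
#' @param tmin,tmax Epoch limits in ms relative to the event sample.
#' @param design Optional [make_design()] table used to attach full
#'   (category, identity, variation) labels by `condition_id`; repetition is
#'   the occurrence index of each condition in event order.
#' @return An [epoched_recording()].
#' @export
epoch_recording <- function(x, tmin, tmax, design = NULL) {
  stopifnot(inherits(x, "continuous_recording"), tmin <= tmax)
  if (nrow(x$events) == 0) stop("recording has no events to epoch around")
  step <- 1000 / x$sfreq
  i0 <- round(tmin / step)
  i1 <- round(tmax / step)
  lo <- x$events$sample + i0
  hi <- x$events$sample + i1
  bad <- which(lo < 1 | hi > ncol(x$data))
  if (length(bad)) {
    stop("epoch window out of bounds for events: ", paste(bad, collapse = ", "))
  }
  n_t <- i1 - i0 + 1
  data <- array(0, dim = c(nrow(x$events), nrow(x$data), n_t))
  for (e in seq_len(nrow(x$events))) {
    data[e, , ] <- x$data[, lo[e]:hi[e], drop = FALSE]
  }
  time_ms <- (i0:i1) * step
  cid <- x$events$condition_id
  labels <- data.frame(condition_id = cid,
                       repetition = stats::ave(cid, cid, FUN = seq_along))
  if (!is.null(design)) {
    lut <- unique(design[, c("condition_id", "category", "identity", "variation")])
    m <- match(labels$condition_id, lut$condition_id)
    if (anyNA(m)) stop("events reference condition_ids absent from design")
    labels <- cbind(lut[m, ], repetition = labels$repetition)
    rownames(labels) <- NULL
  }
  channels <- data.frame(name = x$channels, region = NA_character_,
                         stringsAsFactors = FALSE)
  epoched_recording(data, time_ms, x$sfreq, channels, labels,
                    participant_id = "continuous", modality = "EEG")
}
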