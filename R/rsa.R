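#' Construct a representational dissimilarity matrix object
#'
#' An RDM stores pairwise dissimilarities between experimental conditions:
#' symmetric, diagonal undefined (stored as `NaN`), off-diagonal values in
#' `[0, 2]` for the 1 - Spearman measure.  The upper triangle (row < col) is
#' the canonical vectorization order.
#'
#' @param values Square numeric matrix.
#' @param condition_order Vector of condition ids indexing rows and columns
#'   identically (no duplicates).
#' @param meta Named list of metadata (modality, participant, roi, time_ms).
#' @return Matrix of class `rdm` with attributes `condition_order`, `meta`.
#' @export
rdm <- function(values, condition_order, meta = list()) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("RDM must be square")
  if (length(condition_order) != nrow(values)) {
    stop("condition_order length must match RDM dimension")
  }
  if (anyDuplicated(condition_order)) stop("condition_order has duplicates")
  offdiag <- values[row(values) != col(values)]
  offdiag <- offdiag[!is.na(offdiag)]
  if (length(offdiag) && max(abs(values - t(values)), na.rm = TRUE) > 1e-12) {
    stop("RDM must be symmetric within 1e-12")
  }
  if (length(offdiag) && (min(offdiag) < -1e-12 || max(offdiag) > 2 + 1e-12)) {
    stop("off-diagonal dissimilarities must lie in [0, 2]")
  }
  diag(values) <- NaN
  structure(values, class = c("rdm", "matrix"),
            condition_order = condition_order, meta = meta)
}

#' Upper-triangle vector of an RDM (canonical order, diagonal excluded)
#' @param x An `rdm`.
#' @return Numeric vector of the `upper.tri` entries.
#' @export
rdm_utv <- function(x) {
  x[upper.tri(x)]
}

#' Condition-mean patterns
#'
#' Averages trials across repetitions within each condition.  Rows follow
#' the canonical condition order.
#'
#' @param x An [epoched_recording()] (returns `[condition x channel x time]`)
#'   or a numeric matrix `[trial x feature]` (returns
#'   `[condition x feature]`).
#' @param labels Condition labels (`condition_id` per trial); taken from the
#'   recording when `x` is an `epoched_recording`.
#' @return Averaged array/matrix with attribute `condition_order`.
#' @export
condition_means <- function(x, labels = NULL) {
  if (inherits(x, "epoched_recording")) {
    labels <- x$labels
    dat <- x$data
  } else {
    stopifnot(!is.null(labels))
    dat <- x
  }
  ids <- sort(unique(labels$condition_id))
  if (is.matrix(dat)) {
    out <- matrix(0, length(ids), ncol(dat))
    for (i in seq_along(ids)) {
      rows <- which(labels$condition_id == ids[i])
      out[i, ] <- colMeans(dat[rows, , drop = FALSE])
    }
  } else {
    out <- array(0, dim = c(length(ids), dim(dat)[2], dim(dat)[3]))
    for (i in seq_along(ids)) {
      rows <- which(labels$condition_id == ids[i])
      out[i, , ] <- apply(dat[rows, , , drop = FALSE], c(2, 3), mean)
    }
  }
  attr(out, "condition_order") <- ids
  out
}

#' Compute an RDM from condition patterns
#'
#' Dissimilarity between conditions i and j is `1 - Spearman rank
#' correlation` between their feature patterns (ties by mid-ranks).  Constant
#' patterns have no rank variance: their entries are undefined (`NaN`) and a
#' warning is issued.
#'
#' @param patterns Numeric matrix `[condition x feature]` (>= 3 features).
#' @param condition_order Condition ids for the rows (default: the
#'   `condition_order` attribute, else `1:nrow`).
#' @param meta Metadata list stored on the RDM.
#' @return An [rdm()].
#' @export
compute_rdm <- function(patterns, condition_order = NULL, meta = list()) {
  if (ncol(patterns) < 3) stop("need >= 3 features per condition for rank correlation")
  if (is.null(condition_order)) {
    condition_order <- attr(patterns, "condition_order")
    if (is.null(condition_order)) condition_order <- seq_len(nrow(patterns))
  }
  constant <- apply(patterns, 1, function(r) stats::sd(r) == 0)
  vals <- 1 - suppressWarnings(stats::cor(t(patterns), method = "spearman"))
  if (any(constant)) {
    warning(sum(constant), " constant pattern(s): their dissimilarities are undefined")
    vals[constant, ] <- NaN
    vals[, constant] <- NaN
  }
  rdm(vals, condition_order, meta)
}

#' Time-resolved RDMs from epoched recordings
#'
#' Computes one RDM per timepoint from the channel patterns of the condition
#' means; with several participants, per-participant RDM stacks are averaged
#' elementwise (undefined entries propagate as undefined in the mean).
#'
#' @param recordings An [epoched_recording()] or list of them.
#' @param meta Metadata stored on the stack.
#' @return An `rdm_stack`: list with `values` array
#'   `[condition x condition x time]`, `time_ms`, `condition_order`, `meta`.
#' @export
rdm_timecourse <- function(recordings, meta = list()) {
  if (inherits(recordings, "epoched_recording")) recordings <- list(recordings)
  stacks <- lapply(recordings, function(rec) {
    cm <- condition_means(rec)
    ids <- attr(cm, "condition_order")
    n_t <- dim(cm)[3]
    vals <- array(NA_real_, dim = c(length(ids), length(ids), n_t))
    for (t in seq_len(n_t)) {
      pat <- cm[, , t, drop = FALSE]
      dim(pat) <- dim(cm)[1:2]
      vals[, , t] <- unclass(compute_rdm(pat, ids))
    }
    list(values = vals, ids = ids)
  })
  ids <- stacks[[1]]$ids
  for (s in stacks) {
    if (!identical(s$ids, ids)) stop("condition orders differ across participants")
  }
  mean_vals <- Reduce(`+`, lapply(stacks, `[[`, "values")) / length(stacks)
  structure(list(values = mean_vals, time_ms = recordings[[1]]$time_ms,
                 condition_order = ids, meta = meta),
            class = "rdm_stack")
}

#' Extract the RDM at one timepoint of a stack
#' @param stack An `rdm_stack`.
#' @param t Timepoint index.
#' @return An [rdm()].
#' @export
rdm_at <- function(stack, t) {
  v <- stack$values[, , t]
  ## elementwise means of symmetric matrices stay symmetric up to rounding
  v <- (v + t(v)) / 2
  rdm(v, stack$condition_order,
      c(stack$meta, list(time_ms = stack$time_ms[t])))
}

#' Region-wise ECoG RDM timecourses
#'
#' Splits the pooled super-subject electrodes by region label and computes a
#' time-resolved RDM stack per region.  Empty regions are skipped with a
#' warning; regions with fewer than 3 electrodes warn (rank correlations over
#' so few features are unstable).
#'
#' @param ecog An [epoched_recording()] with region-labeled channels.
#' @param regions Regions to compute (default: all present).
#' @return Named list of `rdm_stack` objects.
#' @export
regional_rdms <- function(ecog, regions = NULL) {
  stopifnot(inherits(ecog, "epoched_recording"))
  have <- unique(stats::na.omit(ecog$channels$region))
  if (is.null(regions)) regions <- have
  out <- list()
  for (r in regions) {
    idx <- which(ecog$channels$region == r)
    if (length(idx) == 0) {
      warning("region ", r, " has no electrodes; skipped")
      next
    }
    if (length(idx) < 3) {
      warning("region ", r, " has fewer than 3 electrodes; RDMs will be unstable")
    }
    sub <- ecog
    sub$data <- ecog$data[, idx, , drop = FALSE]
    sub$channels <- ecog$channels[idx, , drop = FALSE]
    out[[r]] <- rdm_timecourse(sub, meta = list(modality = "ECoG", roi = r))
  }
  out
}

#' Upper-bound noise ceiling of a set of participant RDMs
#'
#' Mean over participants of the Spearman correlation between each
#' participant's RDM (upper-triangle vector) and the group-mean RDM that
#' includes that participant.  Used as a proxy for regional fMRI SNR.
#'
#' @param participant_rdms List of [rdm()] objects (>= 2), same condition
#'   order.
#' @return Scalar in `[-1, 1]`.
#' @export
noise_ceiling_upper <- function(participant_rdms) {
  if (length(participant_rdms) < 2) stop("need >= 2 participants")
  ord <- attr(participant_rdms[[1]], "condition_order")
  for (r in participant_rdms) {
    if (!identical(attr(r, "condition_order"), ord)) {
      stop("condition orders differ across participants")
    }
  }
  utvs <- vapply(participant_rdms, rdm_utv,
                 numeric(length(rdm_utv(participant_rdms[[1]]))))
  group <- rowMeans(utvs)
  cors <- vapply(seq_len(ncol(utvs)), function(i) {
    ok <- is.finite(utvs[, i]) & is.finite(group)
    if (sum(ok) < 3) stop("fewer than 3 valid entry pairs for participant ", i)
    stats::cor(utvs[ok, i], group[ok], method = "spearman")
  }, 0)
  mean(cors)
}
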