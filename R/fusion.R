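#' Overall Spearman correlation between two accuracy timecourses
#'
#' @param tc_a,tc_b Numeric vectors on a common time grid.
#' @param time_ms Optional time axis; when given, only samples with
#'   `time_ms >= post_only_from` enter the correlation (default: post-stimulus
#'   samples only; set `post_only_from = -Inf` for the full epoch).
#' @param post_only_from Earliest time included, in ms.
#' @return Spearman rho.
#' @export
correlate_timecourses <- function(tc_a, tc_b, time_ms = NULL,
                                  post_only_from = 0) {
  stopifnot(length(tc_a) == length(tc_b))
  if (!is.null(time_ms)) {
    keep <- time_ms >= post_only_from
    tc_a <- tc_a[keep]
    tc_b <- tc_b[keep]
  }
  ok <- is.finite(tc_a) & is.finite(tc_b)
  if (sum(ok) < 3) stop("fewer than 3 common timepoints")
  suppressWarnings(stats::cor(tc_a[ok], tc_b[ok], method = "spearman"))
}

#' Bin-average a timecourse onto a coarser grid
#'
#' Averages samples within consecutive bins of `width_ms` and reports bin
#' centers.  Used to align a 1-ms EEG accuracy curve with 25-ms ECoG bins
#' without fabricating temporal resolution by interpolation.
#'
#' @param curve Numeric vector (or matrix `[time x k]`).
#' @param time_ms Time axis.
#' @param width_ms Bin width in ms.
#' @param start_ms First bin edge (default: first sample).
#' @return List with `values` (vector or matrix over bins) and `time_ms`
#'   (bin centers).
#' @export
bin_timecourse <- function(curve, time_ms, width_ms = 25,
                           start_ms = min(time_ms)) {
  idx <- floor((time_ms - start_ms) / width_ms)
  keep <- idx >= 0
  bins <- sort(unique(idx[keep]))
  centers <- start_ms + (bins + 0.5) * width_ms
  if (is.matrix(curve)) {
    vals <- t(vapply(bins, function(b) {
      colMeans(curve[keep & idx == b, , drop = FALSE])
    }, numeric(ncol(curve))))
  } else {
    vals <- vapply(bins, function(b) mean(curve[keep & idx == b]), 0)
  }
  list(values = vals, time_ms = centers)
}

#' Time-resolved category-profile correlation between two modalities
#'
#' At each timepoint, the five per-category accuracies of each modality form
#' a 1 x 5 vector; the two vectors are compared by Spearman correlation,
#' yielding one rho per timepoint.  Constant (fully tied) vectors give an
#' undefined rho, propagated as `NaN`.
#'
#' @param acc_a,acc_b Matrices `[time x category]` with identical category
#'   order.
#' @return A `fusion_timecourse`: list with `rho`, `time_ms` (if supplied via
#'   `time_ms`), `pair`.
#' @param time_ms Optional time axis stored on the result.
#' @param pair Character label of the modality pair.
#' @export
timewise_category_correlation <- function(acc_a, acc_b, time_ms = NULL,
                                          pair = c("a", "b")) {
  stopifnot(ncol(acc_a) == ncol(acc_b), nrow(acc_a) == nrow(acc_b))
  if (!is.null(colnames(acc_a)) && !is.null(colnames(acc_b)) &&
      !identical(colnames(acc_a), colnames(acc_b))) {
    stop("category orders differ")
  }
  rho <- vapply(seq_len(nrow(acc_a)), function(t) {
    a <- acc_a[t, ]; b <- acc_b[t, ]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NaN)
    suppressWarnings(stats::cor(a, b, method = "spearman"))
  }, 0)
  structure(list(rho = rho, time_ms = time_ms, pair = pair),
            class = "fusion_timecourse")
}

#' Fuse a static or time-resolved RDM with an RDM timecourse
#'
#' Correlates (Spearman, upper-triangle vectors) the RDM of every timepoint
#' of `stack_b` with the corresponding member of `a` (a static RDM is
#' broadcast across time).  Significance per timepoint comes from the
#' condition-label permutation test, FDR-corrected over time; undefined rho
#' values are excluded from the FDR family.
#'
#' @param a An [rdm()] (broadcast) or `rdm_stack` with matching time axis.
#' @param stack_b An `rdm_stack`.
#' @param n_perm Permutations per timepoint.
#' @param q FDR level.
#' @param seed Integer seed.
#' @return A `fusion_timecourse`: list with `rho`, `p`, `p_adj`, `mask`,
#'   `time_ms`, `pair`.
#' @export
fuse_rdm_timecourse <- function(a, stack_b, n_perm = 1000, q = 0.05,
                                seed = 1L, pair = c("a", "b")) {
  stopifnot(inherits(stack_b, "rdm_stack"))
  static <- inherits(a, "rdm")
  ord_b <- stack_b$condition_order
  ord_a <- if (static) attr(a, "condition_order") else a$condition_order
  if (!identical(ord_a, ord_b)) stop("condition orders do not match")
  n_t <- dim(stack_b$values)[3]
  if (!static && dim(a$values)[3] != n_t) stop("time axes differ")
  rho <- numeric(n_t)
  p <- numeric(n_t)
  set.seed(seed)
  n <- length(ord_b)
  for (t in seq_len(n_t)) {
    rdm_bt <- stack_b$values[, , t]
    a_t <- if (static) unclass(a) else a$values[, , t]
    utv_a <- a_t[upper.tri(a_t)]
    rho[t] <- spearman_utv(utv_a, rdm_bt[upper.tri(rdm_bt)])
    if (!is.finite(rho[t])) {
      p[t] <- NA_real_
      next
    }
    null <- vapply(seq_len(n_perm), function(i) {
      pm <- sample.int(n)
      spearman_utv(utv_a, rdm_bt[pm, pm][upper.tri(rdm_bt)])
    }, 0)
    p[t] <- (1 + sum(null >= rho[t] - 1e-12, na.rm = TRUE)) / (1 + n_perm)
  }
  mask <- fdr_correct(p, q = q)
  structure(list(rho = rho, p = p, p_adj = mask$p_adj, mask = mask$mask,
                 time_ms = stack_b$time_ms, pair = pair),
            class = "fusion_timecourse")
}

#' Region-wise SNR vs cross-modal correspondence
#'
#' For each of the six canonical regions, correlates (Spearman over the five
#' per-category accuracies) the fMRI and ECoG category-selectivity decoding
#' profiles, and pairs that correspondence with the region's fMRI SNR proxy
#' (the upper-bound noise ceiling of the participant RDMs).  The summary is
#' the Spearman correlation between the six correspondences and the six SNR
#' values.
#'
#' @param fmri_acc,ecog_acc Matrices `[region x category]` of mean decoding
#'   accuracies (rows named by [nf_rois], columns by category).
#' @param fmri_rdms Named list (per region) of lists of participant
#'   [rdm()] objects.
#' @return A `region_correspondence`: data.frame with `region`, `rho`
#'   (ECoG-fMRI correspondence) and `fmri_snr`, plus attribute
#'   `summary_rho` (NA, flagged, if either 6-vector is constant).
#' @export
snr_vs_correspondence <- function(fmri_acc, ecog_acc, fmri_rdms) {
  missing <- setdiff(nf_rois, rownames(fmri_acc))
  if (length(missing)) stop("fmri_acc missing ROIs: ", paste(missing, collapse = ", "))
  missing <- setdiff(nf_rois, rownames(ecog_acc))
  if (length(missing)) stop("ecog_acc missing ROIs: ", paste(missing, collapse = ", "))
  missing <- setdiff(nf_rois, names(fmri_rdms))
  if (length(missing)) stop("fmri_rdms missing ROIs: ", paste(missing, collapse = ", "))
  rho <- vapply(nf_rois, function(r) {
    a <- fmri_acc[r, ]; b <- ecog_acc[r, ]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NaN)
    suppressWarnings(stats::cor(a, b, method = "spearman"))
  }, 0)
  snr <- vapply(nf_rois, function(r) noise_ceiling_upper(fmri_rdms[[r]]), 0)
  ok <- is.finite(rho) & is.finite(snr)
  summary_rho <- if (sum(ok) >= 3 && stats::sd(rho[ok]) > 0 && stats::sd(snr[ok]) > 0) {
    suppressWarnings(stats::cor(rho[ok], snr[ok], method = "spearman"))
  } else {
    NA_real_
  }
  structure(data.frame(region = nf_rois, rho = rho, fmri_snr = snr,
                       row.names = NULL),
            summary_rho = summary_rho, class = c("region_correspondence",
                                                 "data.frame"))
}
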