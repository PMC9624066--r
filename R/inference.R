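#' One-sided Wilcoxon signed-rank test of accuracies against chance
#'
#' Tests, at each timepoint, whether the per-participant accuracies exceed
#' the chance constant, with the one-sided (greater) signed-rank test.  Zero
#' differences are dropped (standard signed-rank convention) and their count
#' is recorded; a timepoint with all-zero differences gets `p = 1`.  The
#' exact null distribution is used for `n <= 25` untied samples, the normal
#' approximation above that (or when ties/zeros force it).
#'
#' @param acc Numeric matrix `[participant x timepoint]` (>= 5 participants).
#' @param chance Chance level, default 0.5.
#' @return Numeric vector of one-sided p-values per timepoint, with
#'   attribute `n_zero` (dropped zero-differences per timepoint).
#' @export
wilcoxon_above_chance <- function(acc, chance = 0.5) {
  stopifnot(is.matrix(acc))
  if (nrow(acc) < 5) stop("need >= 5 participants")
  n_zero <- integer(ncol(acc))
  p <- vapply(seq_len(ncol(acc)), function(t) {
    d <- acc[, t] - chance
    n_zero[t] <<- sum(d == 0)
    d <- d[d != 0]
    if (length(d) == 0) return(1)
    exact <- length(d) <= 25 && !anyDuplicated(abs(d))
    suppressWarnings(
      stats::wilcox.test(d, alternative = "greater", mu = 0,
                         exact = exact)$p.value
    )
  }, 0)
  attr(p, "n_zero") <- n_zero
  p
}

#' Benjamini-Hochberg FDR correction over one curve
#'
#' Step-up false-discovery-rate control over the supplied family (typically
#' all timepoints of one accuracy or correlation curve).
#'
#' @param p Vector of p-values in `[0, 1]` (NA entries are excluded from the
#'   family and stay unmasked).
#' @param q FDR level, default 0.05.
#' @return A `significance_mask`: list with `p`, `p_adj`, `mask`, `q`.
#' @export
fdr_correct <- function(p, q = 0.05) {
  if (length(p) == 0) stop("empty p-value vector")
  finite <- is.finite(p)
  if (any(p[finite] < 0 | p[finite] > 1)) stop("p-values must lie in [0, 1]")
  p_adj <- rep(NA_real_, length(p))
  p_adj[finite] <- stats::p.adjust(p[finite], method = "BH")
  mask <- !is.na(p_adj) & p_adj <= q
  structure(list(p = p, p_adj = p_adj, mask = mask, q = q),
            class = "significance_mask")
}

#' Onset latency: first sustained run of significant timepoints
#'
#' The earliest time opening a run of at least `min_run` consecutive
#' significant samples.  The search starts at stimulus onset (`t >= 0`);
#' pre-stimulus significances count only toward calibration checks.
#'
#' @param mask A `significance_mask` or logical vector.
#' @param time_ms Time axis aligned with the mask.
#' @param min_run Minimum run length in samples (default 15, i.e. 15 ms on a
#'   1 kHz grid).
#' @param search_start_ms Earliest time considered (default 0).
#' @return Onset time in ms, or `NA` if no qualifying run exists.
#' @export
onset_latency <- function(mask, time_ms, min_run = 15, search_start_ms = 0) {
  if (inherits(mask, "significance_mask")) mask <- mask$mask
  stopifnot(length(mask) == length(time_ms))
  keep <- time_ms >= search_start_ms
  m <- mask[keep]
  tt <- time_ms[keep]
  if (!any(m)) return(NA_real_)
  r <- rle(m)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  ok <- which(r$values & r$lengths >= min_run)
  if (length(ok) == 0) return(NA_real_)
  tt[starts[ok[1]]]
}

#' Peak latency of a decoding/correlation curve
#'
#' Time of the global maximum within the search window; ties are broken
#' toward the earliest timepoint.
#'
#' @param curve Numeric vector.
#' @param time_ms Time axis.
#' @param window Search window in ms (default: all post-stimulus times).
#' @return Peak time in ms.
#' @export
peak_latency <- function(curve, time_ms, window = c(0, Inf)) {
  stopifnot(length(curve) == length(time_ms), length(curve) > 0)
  keep <- which(time_ms >= window[1] & time_ms <= window[2])
  if (length(keep) == 0) stop("empty search window")
  ## which.max returns the earliest index among tied maxima
  time_ms[keep[which.max(curve[keep])]]
}

#' Bootstrap resampling of participants
#'
#' Resamples participants with replacement, applies `stat_fn` to each
#' resample, and returns the empirical distribution, the 95% percentile
#' confidence interval, and (for difference statistics) a two-sided p-value
#' `2 * min(P(s* <= 0), P(s* >= 0))` with +1 smoothing.
#'
#' @param data Participant-indexed data: a matrix (rows = participants) or a
#'   list with one element per participant.
#' @param stat_fn Function mapping a participant resample (same structure as
#'   `data`) to a scalar.
#' @param n_boot Number of bootstrap resamples (default 10000).
#' @param seed Integer seed.
#' @param conf Confidence level for the percentile interval.
#' @return List with `distribution`, `ci`, `p`, `n_boot`, `n_undefined`.
#' @export
bootstrap_participants <- function(data, stat_fn, n_boot = 10000, seed = 1L,
                                   conf = 0.95) {
  n <- if (is.matrix(data)) nrow(data) else length(data)
  stopifnot(n >= 2)
  set.seed(seed)
  take <- if (is.matrix(data)) {
    function(idx) data[idx, , drop = FALSE]
  } else {
    function(idx) data[idx]
  }
  dist <- vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    as.numeric(stat_fn(take(idx)))
  }, 0)
  n_undef <- sum(!is.finite(dist))
  if (n_undef > n_boot / 2) {
    stop("statistic undefined on ", n_undef, " of ", n_boot,
         " resamples; cannot summarize")
  }
  ok <- dist[is.finite(dist)]
  alpha <- (1 - conf) / 2
  ci <- stats::quantile(ok, c(alpha, 1 - alpha), names = FALSE, type = 7)
  p <- 2 * min((1 + sum(ok <= 0)) / (1 + length(ok)),
               (1 + sum(ok >= 0)) / (1 + length(ok)))
  list(distribution = dist, ci = ci, p = min(p, 1), n_boot = n_boot,
       n_undefined = n_undef)
}

#' Condition-label permutation test of an RDM-to-RDM correlation
#'
#' The observed statistic is the Spearman correlation between the
#' upper-triangle vectors of the two RDMs.  The null is built by jointly
#' permuting rows and columns (i.e. condition labels) of the second RDM;
#' the one-sided p-value is `(1 + #{rho* >= rho_obs}) / (1 + n_perm)`.
#'
#' @param rdm_a,rdm_b [rdm()] objects with identical `condition_order`
#'   (mismatches are rejected, never silently realigned).
#' @param n_perm Number of random permutations (default 10000).
#' @param seed Integer seed.
#' @param exhaustive Use all `n!` permutations instead (small designs only).
#' @return List with `rho`, `p`, `null` (the null distribution).
#' @export
permutation_rdm_test <- function(rdm_a, rdm_b, n_perm = 10000, seed = 1L,
                                 exhaustive = FALSE) {
  ord_a <- attr(rdm_a, "condition_order")
  ord_b <- attr(rdm_b, "condition_order")
  if (!identical(ord_a, ord_b)) stop("condition orders do not match")
  a <- rdm_utv(rdm_a)
  n <- nrow(rdm_a)
  rho_obs <- spearman_utv(a, rdm_utv(rdm_b))
  bmat <- unclass(rdm_b)
  if (exhaustive) {
    perms <- all_permutations(n)
    null <- vapply(perms, function(pm) {
      spearman_utv(a, bmat[pm, pm][upper.tri(bmat)])
    }, 0)
    p <- mean(null >= rho_obs - 1e-12)
  } else {
    set.seed(seed)
    null <- vapply(seq_len(n_perm), function(i) {
      pm <- sample.int(n)
      spearman_utv(a, bmat[pm, pm][upper.tri(bmat)])
    }, 0)
    p <- (1 + sum(null >= rho_obs - 1e-12)) / (1 + n_perm)
  }
  list(rho = rho_obs, p = p, null = null)
}

spearman_utv <- function(a, b) {
  ok <- is.finite(a) & is.finite(b)
  if (sum(ok) < 3) return(NA_real_)
  suppressWarnings(stats::cor(a[ok], b[ok], method = "spearman"))
}

all_permutations <- function(n) {
  if (n > 8) stop("exhaustive permutation only supported for n <= 8")
  if (n == 1) return(list(1L))
  sub <- all_permutations(n - 1)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (s in sub) {
    for (pos in seq_len(n)) {
      k <- k + 1L
      out[[k]] <- append(s, n, after = pos - 1L)
    }
  }
  out
}

#' Significance timecourse of group decoding accuracy
#'
#' Convenience wrapper: per-timepoint one-sided Wilcoxon signed-rank test of
#' participant accuracies against chance, FDR-corrected over the curve, with
#' onset and peak latency extraction.
#'
#' @param result A `decoding_result` from [decode_timecourse()].
#' @param chance Chance level.
#' @param q FDR level.
#' @param min_run Minimum run length for onset latency, in samples.
#' @return List with `p`, `mask` (a `significance_mask`), `onset_ms`,
#'   `peak_ms`, `curve` (group mean accuracy) and `time_ms`.
#' @export
significance_timecourse <- function(result, chance = 0.5, q = 0.05,
                                    min_run = 15) {
  acc <- participant_accuracy(result)
  p <- wilcoxon_above_chance(acc, chance = chance)
  mask <- fdr_correct(p, q = q)
  curve <- group_accuracy(result)
  list(p = p, mask = mask,
       onset_ms = onset_latency(mask, result$time_ms, min_run = min_run),
       peak_ms = peak_latency(curve, result$time_ms),
       curve = curve, time_ms = result$time_ms)
}
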