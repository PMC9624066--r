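#' Classification schemes
#'
#' The three one-vs-rest classification schemes used throughout:
#' * `category_selectivity` — train and test on all five viewing conditions;
#' * `rotation_invariance` — train on the reference condition (3 deg size,
#'   0 deg rotation, `v1`) and test on the rotated versions (`v2`, `v3`),
#'   averaging the two test results;
#' * `scale_invariance` — train on `v1`, test on the rescaled versions
#'   (`v4`, `v5`), averaging the two.
#'
#' @param name Scheme name.
#' @return List of class `decode_scheme` with `name`, `train_variations`,
#'   `test_variations`.
#' @export
decode_scheme <- function(name = c("category_selectivity",
                                   "rotation_invariance",
                                   "scale_invariance")) {
  name <- match.arg(name)
  sch <- switch(name,
    category_selectivity = list(train = nf_variations, test = nf_variations),
    rotation_invariance  = list(train = "v1", test = c("v2", "v3")),
    scale_invariance     = list(train = "v1", test = c("v4", "v5"))
  )
  structure(list(name = name, train_variations = sch$train,
                 test_variations = sch$test),
            class = "decode_scheme")
}

#' Decoding parameters
#'
#' @param n_pseudotrials Number of pseudo-trial sets formed per class in the
#'   category-selectivity scheme (default 150; capped at the class trial
#'   count).
#' @param n_repeats Number of repeats of the balance/partition procedure.
#'   `NULL` resolves per scheme at decode time: 300 for category selectivity,
#'   150 for the invariance schemes.
#' @param cost Regularization constant `C` of the linear max-margin
#'   classifier (fixed default 1; logged in provenance).
#' @param whiten Apply multivariate noise normalization (estimated from
#'   training data only)?
#' @param shrinkage Shrinkage weight toward the scaled identity in the noise
#'   covariance estimate, in \[0, 1\].
#' @param max_folds Upper bound on the number of leave-one-out folds
#'   actually evaluated (a seeded random subset; Monte-Carlo
#'   cross-validation).  `Inf` evaluates every fold.
#' @param seed Integer seed for balancing/partitioning randomness.
#' @return List of class `decoding_params`.
#' @export
decoding_params <- function(n_pseudotrials = 150, n_repeats = NULL, cost = 1,
                            whiten = TRUE, shrinkage = 0.2, max_folds = Inf,
                            seed = 1L) {
  stopifnot(n_pseudotrials >= 2, cost > 0, shrinkage >= 0, shrinkage <= 1,
            max_folds >= 2)
  if (!is.null(n_repeats) && n_repeats < 1) stop("n_repeats must be >= 1")
  structure(list(n_pseudotrials = as.integer(n_pseudotrials),
                 n_repeats = n_repeats, cost = cost, whiten = whiten,
                 shrinkage = shrinkage, max_folds = max_folds,
                 seed = as.integer(seed)),
            class = "decoding_params")
}

resolve_repeats <- function(params, scheme) {
  if (!is.null(params$n_repeats)) return(as.integer(params$n_repeats))
  if (scheme$name == "category_selectivity") 300L else 150L
}

#' Balance a one-vs-rest contrast by subsampling negatives
#'
#' @param categories Character vector of per-trial category labels.
#' @param target Target (positive) category.
#' @param seed Optional seed; when `NULL` the current RNG stream is used.
#' @return List with `pos` (indices of the target trials) and `neg` (an
#'   equally sized uniform subsample, without replacement, of the rest).
#' @export
balance_one_vs_rest <- function(categories, target, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pos <- which(categories == target)
  negpool <- which(categories != target)
  if (length(pos) == 0) stop("no trials of target category ", target)
  if (length(negpool) < length(pos)) {
    stop("fewer negative than positive trials (", length(negpool), " < ",
         length(pos), ")")
  }
  neg <- if (length(negpool) == length(pos)) negpool
         else sort(sample(negpool, length(pos)))
  list(pos = pos, neg = neg)
}

#' Average trials into pseudo-trials
#'
#' Randomly partitions the trials into `n_sets` sets whose sizes differ by at
#' most one (no trial reused) and averages within each set.
#'
#' @param x Trials: matrix `[trial x feature]` or array
#'   `[trial x channel x time]`.
#' @param n_sets Number of pseudo-trials to form (`<=` trial count).
#' @param seed Optional seed; when `NULL` the current RNG stream is used.
#' @return Same structure as `x` with `n_sets` leading rows; attribute
#'   `set_sizes` records the partition sizes.
#' @export
make_pseudotrials <- function(x, n_sets, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- dim(x)[1]
  if (n_sets > n) stop("n_sets (", n_sets, ") exceeds trial count (", n, ")")
  assignment <- sample(rep(seq_len(n_sets), length.out = n))
  if (length(dim(x)) == 2) {
    out <- matrix(0, n_sets, ncol(x))
    for (s in seq_len(n_sets)) {
      out[s, ] <- colMeans(x[assignment == s, , drop = FALSE])
    }
  } else {
    out <- array(0, dim = c(n_sets, dim(x)[2], dim(x)[3]))
    for (s in seq_len(n_sets)) {
      sel <- which(assignment == s)
      out[s, , ] <- apply(x[sel, , , drop = FALSE], c(2, 3), mean)
    }
  }
  attr(out, "set_sizes") <- as.integer(table(assignment))
  out
}

#' Multivariate noise normalization (whitening)
#'
#' Estimates a shrinkage-regularized channel noise covariance from training
#' residuals (per-class, per-timepoint covariances averaged over timepoints
#' and classes) and applies `W = Sigma^(-1/2)` to train and test patterns.
#' The covariance is estimated from the training data only, so the test fold
#' never leaks into the transform.
#'
#' @param train Training patterns, matrix `[trial x channel]` or array
#'   `[trial x channel x time]`.
#' @param test Optional test patterns to transform with the same `W`.
#' @param classes Optional per-trial class labels for residual computation;
#'   `NULL` treats all training trials as one class.
#' @param shrinkage Shrinkage weight toward `mean(diag(Sigma)) * I`.
#' @param sigma Optional known covariance matrix (overrides estimation; no
#'   shrinkage applied).
#' @return List with whitened `train`, `test`, the transform `W` and the
#'   `condition_number` of the (regularized) covariance.
#' @export
noise_normalize <- function(train, test = NULL, classes = NULL,
                            shrinkage = 0.2, sigma = NULL) {
  as3d <- function(x) if (length(dim(x)) == 2) array(x, dim = c(dim(x), 1)) else x
  was_mat <- length(dim(train)) == 2
  tr <- as3d(train)
  n_ch <- dim(tr)[2]
  if (is.null(sigma)) {
    if (is.null(classes)) classes <- rep(1L, dim(tr)[1])
    sigma <- matrix(0, n_ch, n_ch)
    n_terms <- 0L
    for (cl in unique(classes)) {
      rows <- which(classes == cl)
      if (length(rows) < 2) next
      for (t in seq_len(dim(tr)[3])) {
        xm <- tr[rows, , t, drop = FALSE]
        dim(xm) <- c(length(rows), n_ch)
        sigma <- sigma + stats::cov(xm)
        n_terms <- n_terms + 1L
      }
    }
    if (n_terms == 0L) {
      ## no class has two trials (e.g. tiny leave-one-out folds): fall back
      ## to pooled residuals around the grand mean
      if (dim(tr)[1] < 2) stop("covariance not estimable: need >= 2 training trials")
      for (t in seq_len(dim(tr)[3])) {
        xm <- tr[, , t, drop = FALSE]
        dim(xm) <- dim(tr)[1:2]
        sigma <- sigma + stats::cov(xm)
        n_terms <- n_terms + 1L
      }
    }
    sigma <- sigma / n_terms
    sigma <- (1 - shrinkage) * sigma + shrinkage * mean(diag(sigma)) * diag(n_ch)
  }
  eig <- eigen(sigma, symmetric = TRUE)
  vals <- pmax(eig$values, max(eig$values) * 1e-10)
  w <- eig$vectors %*% diag(1 / sqrt(vals), n_ch) %*% t(eig$vectors)
  cond <- max(vals) / min(vals)
  apply_w <- function(x) {
    if (is.null(x)) return(NULL)
    x3 <- as3d(x)
    out <- array(0, dim = dim(x3))
    for (t in seq_len(dim(x3)[3])) {
      xm <- x3[, , t, drop = FALSE]
      dim(xm) <- dim(x3)[1:2]
      out[, , t] <- xm %*% w
    }
    if (length(dim(x)) == 2) out[, , 1] else out
  }
  list(train = if (was_mat) apply_w(train) else apply_w(tr),
       test = apply_w(test), W = w, condition_number = cond)
}

## Linear max-margin fit + deterministic prediction: decision-value ties are
## broken toward the negative ("rest") class.  Decision values are computed
## directly from the support-vector expansion (w = coefs' SV, offset rho),
## which for a linear kernel equals predict()'s decision values.
svm_predict <- function(train_x, train_y, test_x, cost) {
  fit <- e1071::svm(x = train_x, y = train_y, kernel = "linear", cost = cost,
                    scale = FALSE, fitted = FALSE, na.action = identity)
  if (is.null(dim(test_x))) test_x <- matrix(test_x, nrow = 1)
  w <- crossprod(fit$coefs, fit$SV)
  dv <- drop(test_x %*% t(w)) - fit$rho
  ## positive decision values belong to the class libsvm saw first
  first <- fit$levels[fit$labels[1]]
  score <- if (identical(first, "target")) dv else -dv
  factor(ifelse(score > 0, "target", "rest"), levels = c("target", "rest"))
}

bind_trials <- function(a, b) {
  out <- array(0, dim = c(dim(a)[1] + dim(b)[1], dim(a)[2], dim(a)[3]))
  out[seq_len(dim(a)[1]), , ] <- a
  out[dim(a)[1] + seq_len(dim(b)[1]), , ] <- b
  out
}

#' Time-resolved one-vs-rest category decoding
#'
#' For every participant, repeat, category and timepoint: balance the
#' one-vs-rest contrast, raise SNR by pseudo-trial averaging (category
#' selectivity scheme only), whiten with training-data noise normalization,
#' train a linear max-margin classifier on the training patterns of that
#' timepoint and evaluate on held-out data.  Category selectivity uses
#' leave-one-pseudo-trial-out cross-validation; the invariance schemes train
#' on all reference-condition trials and test every trial of the held-out
#' viewing conditions, averaging the two test conditions.  Chance is 0.5.
#'
#' @param recordings An [epoched_recording()] or list of them (participants).
#' @param scheme A [decode_scheme()].
#' @param params A [decoding_params()].
#' @return A `decoding_result` with accuracy array
#'   `[participant x category x time]`.
#' @export
decode_timecourse <- function(recordings, scheme, params = decoding_params()) {
  if (inherits(recordings, "epoched_recording")) recordings <- list(recordings)
  stopifnot(inherits(scheme, "decode_scheme"), inherits(params, "decoding_params"))
  first <- recordings[[1]]
  cats <- sort(unique(first$labels$category))
  acc <- array(NA_real_, dim = c(length(recordings), length(cats),
                                 length(first$time_ms)))
  for (i in seq_along(recordings)) {
    acc[i, , ] <- decode_timecourse_one(recordings[[i]], scheme, params,
                                        seed_offset = i)
  }
  structure(list(accuracy = acc, categories = cats, time_ms = first$time_ms,
                 scheme = scheme$name, params = params,
                 participant_ids = vapply(recordings, `[[`, "",
                                          "participant_id")),
            class = "decoding_result")
}

decode_timecourse_one <- function(rec, scheme, params, seed_offset = 0L) {
  labels <- rec$labels
  cats <- sort(unique(labels$category))
  vars_present <- unique(labels$variation)
  test_vars <- intersect(scheme$test_variations, vars_present)
  train_vars <- intersect(scheme$train_variations, vars_present)
  if (scheme$name != "category_selectivity" && length(test_vars) == 0) {
    stop("scheme ", scheme$name, " requires test variations ",
         paste(scheme$test_variations, collapse = "/"), " absent from data")
  }
  if (length(train_vars) == 0) stop("no training variations present in data")
  n_rep <- resolve_repeats(params, scheme)
  n_t <- length(rec$time_ms)
  set.seed(params$seed + 1000L * seed_offset)
  acc <- matrix(0, length(cats), n_t)
  for (r in seq_len(n_rep)) {
    for (ci in seq_along(cats)) {
      if (scheme$name == "category_selectivity") {
        acc[ci, ] <- acc[ci, ] +
          decode_selectivity_once(rec, labels, train_vars, cats[ci], params)
      } else {
        acc[ci, ] <- acc[ci, ] +
          decode_invariance_once(rec, labels, train_vars, test_vars,
                                 cats[ci], params)
      }
    }
  }
  acc / n_rep
}

decode_selectivity_once <- function(rec, labels, train_vars, target, params) {
  pool <- which(labels$variation %in% train_vars)
  b <- balance_one_vs_rest(labels$category[pool], target)
  pos <- pool[b$pos]; neg <- pool[b$neg]
  n_sets <- min(params$n_pseudotrials, length(pos))
  if (n_sets < 2) stop("need at least 2 pseudo-trials for leave-one-out")
  pp <- make_pseudotrials(rec$data[pos, , , drop = FALSE], n_sets)
  pn <- make_pseudotrials(rec$data[neg, , , drop = FALSE], n_sets)
  x <- bind_trials(pp, pn)
  y <- factor(rep(c("target", "rest"), each = n_sets),
              levels = c("target", "rest"))
  n_t <- dim(x)[3]
  ## Fold f holds out the f-th pseudo-trial of EACH class, so the training
  ## set stays exactly balanced in every fold and the null is calibrated.
  fold_set <- seq_len(n_sets)
  if (is.finite(params$max_folds) && params$max_folds < n_sets) {
    fold_set <- sort(sample(fold_set, params$max_folds))
  }
  correct <- matrix(0, length(fold_set), n_t)
  for (fi in seq_along(fold_set)) {
    f <- fold_set[fi]
    te_idx <- c(f, n_sets + f)
    tr_idx <- setdiff(seq_len(2L * n_sets), te_idx)
    xtr <- x[tr_idx, , , drop = FALSE]
    xte <- x[te_idx, , , drop = FALSE]
    if (params$whiten) {
      nn <- noise_normalize(xtr, xte, classes = y[tr_idx],
                            shrinkage = params$shrinkage)
      xtr <- nn$train; xte <- nn$test
    }
    for (t in seq_len(n_t)) {
      trm <- xtr[, , t, drop = FALSE]; dim(trm) <- dim(xtr)[1:2]
      tem <- xte[, , t, drop = FALSE]; dim(tem) <- dim(xte)[1:2]
      pred <- svm_predict(trm, y[tr_idx], tem, params$cost)
      correct[fi, t] <- mean(pred == y[te_idx])
    }
  }
  colMeans(correct)
}

decode_invariance_once <- function(rec, labels, train_vars, test_vars,
                                   target, params) {
  pool <- which(labels$variation %in% train_vars)
  b <- balance_one_vs_rest(labels$category[pool], target)
  tr_idx <- c(pool[b$pos], pool[b$neg])
  y <- factor(rep(c("target", "rest"), c(length(b$pos), length(b$neg))),
              levels = c("target", "rest"))
  xtr <- rec$data[tr_idx, , , drop = FALSE]

  ## balanced test sets, one per held-out viewing condition
  test_sets <- lapply(test_vars, function(tv) {
    tpool <- which(labels$variation == tv)
    tb <- balance_one_vs_rest(labels$category[tpool], target)
    idx <- c(tpool[tb$pos], tpool[tb$neg])
    list(idx = idx,
         y = factor(rep(c("target", "rest"),
                        c(length(tb$pos), length(tb$neg))),
                    levels = c("target", "rest")))
  })
  all_test <- unlist(lapply(test_sets, `[[`, "idx"))
  xte <- rec$data[all_test, , , drop = FALSE]
  if (params$whiten) {
    nn <- noise_normalize(xtr, xte, classes = y, shrinkage = params$shrinkage)
    xtr <- nn$train; xte <- nn$test
  }
  n_t <- dim(xtr)[3]
  acc_v <- matrix(0, length(test_sets), n_t)
  offsets <- cumsum(c(0, vapply(test_sets, function(s) length(s$idx), 0L)))
  for (t in seq_len(n_t)) {
    trm <- xtr[, , t, drop = FALSE]; dim(trm) <- dim(xtr)[1:2]
    tem <- xte[, , t, drop = FALSE]; dim(tem) <- dim(xte)[1:2]
    pred <- svm_predict(trm, y, tem, params$cost)
    for (v in seq_along(test_sets)) {
      rows <- (offsets[v] + 1):offsets[v + 1]
      acc_v[v, t] <- mean(pred[rows] == test_sets[[v]]$y)
    }
  }
  colMeans(acc_v)
}

#' ECoG range features in fixed time bins
#'
#' Builds one feature per electrode per bin: the signal range
#' `max(x) - min(x)` over the samples falling in that bin.  Bins of `bin_ms`
#' tile `[window[1], window[2])` half-open, so a 50-300 ms window with 25 ms
#' bins yields 10 bins per electrode.
#'
#' @param epochs An [epoched_recording()].
#' @param window Feature window in ms, default `c(50, 300)`.
#' @param bin_ms Bin width in ms; the window length must be divisible by it.
#' @param electrodes Optional character vector of electrode names to keep.
#' @return List with `features` (`[trial x electrode*bin]` matrix with
#'   descriptive column names), `labels`, `electrodes` and `bin_starts_ms`.
#' @export
ecog_feature_vector <- function(epochs, window = c(50, 300), bin_ms = 25,
                                electrodes = NULL) {
  stopifnot(inherits(epochs, "epoched_recording"))
  len <- window[2] - window[1]
  if (len <= 0 || abs(len %% bin_ms) > 1e-9) {
    stop("window length must be a positive multiple of bin_ms")
  }
  if (window[1] < min(epochs$time_ms) || window[2] > max(epochs$time_ms) + 1000 / epochs$sfreq) {
    stop("feature window exceeds the epoch")
  }
  keep <- seq_len(nrow(epochs$channels))
  if (!is.null(electrodes)) {
    keep <- match(electrodes, epochs$channels$name)
    if (anyNA(keep)) stop("unknown electrode name(s)")
  }
  n_bins <- as.integer(round(len / bin_ms))
  starts <- window[1] + bin_ms * (seq_len(n_bins) - 1)
  n_trial <- dim(epochs$data)[1]
  feats <- matrix(0, n_trial, length(keep) * n_bins)
  cn <- character(length(keep) * n_bins)
  col <- 0L
  for (e in seq_along(keep)) {
    for (bn in seq_len(n_bins)) {
      col <- col + 1L
      sel <- epochs$time_ms >= starts[bn] & epochs$time_ms < starts[bn] + bin_ms
      seg <- epochs$data[, keep[e], sel, drop = FALSE]
      dim(seg) <- c(n_trial, sum(sel))
      feats[, col] <- apply(seg, 1, max) - apply(seg, 1, min)
      cn[col] <- sprintf("%s_bin%02d", epochs$channels$name[keep[e]], bn)
    }
  }
  colnames(feats) <- cn
  list(features = feats, labels = epochs$labels,
       electrodes = epochs$channels$name[keep], bin_starts_ms = starts)
}

#' Static one-vs-rest decoding of activation patterns
#'
#' Decodes static patterns (fMRI betas or ECoG range-feature vectors) in the
#' same three schemes as [decode_timecourse()].  The category-selectivity
#' scheme uses leave-one-run-out cross-validation when `cv = "run"` (run
#' labels required) or leave-one-trial-out over the balanced pool when
#' `cv = "trial"`; the invariance schemes train on the reference viewing
#' condition and test each trial of the held-out conditions.  Test sets are
#' balanced (target vs an equally sized negative subsample) so chance is 0.5.
#'
#' @param x A [pattern_set()], or a feature matrix `[trial x feature]`.
#' @param labels `condition_table` rows for the feature-matrix interface.
#' @param scheme A [decode_scheme()].
#' @param params A [decoding_params()]; whitening defaults off for static
#'   patterns unless `params$whiten` is set.
#' @param cv `"run"` for leave-one-run-out, `"trial"` for
#'   leave-one-trial-out.
#' @return A `decoding_result` with a single (static) timepoint.
#' @export
decode_static <- function(x, scheme, params = decoding_params(whiten = FALSE),
                          cv = c("run", "trial"), labels = NULL) {
  cv <- match.arg(cv)
  if (inherits(x, "pattern_set")) {
    labels <- x$labels
    if (!"category" %in% names(labels)) {
      labels$category <- condition_category(labels$condition_id)
      labels$variation <- condition_variation(labels$condition_id)
    }
    feats <- x$betas
    pid <- x$participant_id
  } else {
    stopifnot(is.matrix(x), !is.null(labels))
    feats <- x
    pid <- "pooled"
  }
  cats <- sort(unique(labels$category))
  n_rep <- resolve_repeats(params, scheme)
  set.seed(params$seed)
  acc <- vapply(cats, function(ct) {
    a <- 0
    for (r in seq_len(n_rep)) {
      a <- a + decode_static_once(feats, labels, scheme, ct, params, cv)
    }
    a / n_rep
  }, 0)
  structure(list(accuracy = array(acc, dim = c(1, length(cats), 1)),
                 categories = cats, time_ms = NA_real_, scheme = scheme$name,
                 params = params, participant_ids = pid,
                 cv = cv),
            class = "decoding_result")
}

decode_static_once <- function(feats, labels, scheme, target, params, cv) {
  whiten_fit <- function(xtr, ytr, xte) {
    if (!params$whiten) return(list(train = xtr, test = xte))
    nn <- noise_normalize(xtr, xte, classes = ytr, shrinkage = params$shrinkage)
    list(train = nn$train, test = nn$test)
  }
  if (scheme$name == "category_selectivity") {
    if (cv == "run") {
      if (!"run" %in% names(labels)) stop("leave-one-run-out requires run labels")
      runs <- sort(unique(labels$run))
      if (length(runs) < 2) stop("leave-one-run-out requires at least 2 runs")
      fold_acc <- vapply(runs, function(ro) {
        tr_pool <- which(labels$run != ro)
        te_pool <- which(labels$run == ro)
        b <- balance_one_vs_rest(labels$category[tr_pool], target)
        tb <- balance_one_vs_rest(labels$category[te_pool], target)
        xtr <- feats[c(tr_pool[b$pos], tr_pool[b$neg]), , drop = FALSE]
        ytr <- factor(rep(c("target", "rest"), c(length(b$pos), length(b$neg))),
                      levels = c("target", "rest"))
        xte <- feats[c(te_pool[tb$pos], te_pool[tb$neg]), , drop = FALSE]
        yte <- factor(rep(c("target", "rest"), c(length(tb$pos), length(tb$neg))),
                      levels = c("target", "rest"))
        w <- whiten_fit(xtr, ytr, xte)
        mean(svm_predict(w$train, ytr, w$test, params$cost) == yte)
      }, 0)
      mean(fold_acc)
    } else {
      b <- balance_one_vs_rest(labels$category, target)
      idx <- c(b$pos, b$neg)
      n_pos <- length(b$pos)
      y <- factor(rep(c("target", "rest"), c(n_pos, length(b$neg))),
                  levels = c("target", "rest"))
      ## paired leave-one-out: hold out one trial per class per fold so the
      ## training set stays balanced
      folds <- seq_len(n_pos)
      if (is.finite(params$max_folds) && params$max_folds < n_pos) {
        folds <- sort(sample(folds, params$max_folds))
      }
      correct <- vapply(folds, function(f) {
        te <- c(f, n_pos + f)
        w <- whiten_fit(feats[idx[-te], , drop = FALSE], y[-te],
                        feats[idx[te], , drop = FALSE])
        mean(svm_predict(w$train, y[-te], w$test, params$cost) == y[te])
      }, 0)
      mean(correct)
    }
  } else {
    tr_pool <- which(labels$variation %in% scheme$train_variations)
    b <- balance_one_vs_rest(labels$category[tr_pool], target)
    xtr <- feats[c(tr_pool[b$pos], tr_pool[b$neg]), , drop = FALSE]
    ytr <- factor(rep(c("target", "rest"), c(length(b$pos), length(b$neg))),
                  levels = c("target", "rest"))
    accs <- vapply(intersect(scheme$test_variations, unique(labels$variation)),
                   function(tv) {
      te_pool <- which(labels$variation == tv)
      tb <- balance_one_vs_rest(labels$category[te_pool], target)
      xte <- feats[c(te_pool[tb$pos], te_pool[tb$neg]), , drop = FALSE]
      yte <- factor(rep(c("target", "rest"), c(length(tb$pos), length(tb$neg))),
                    levels = c("target", "rest"))
      w <- whiten_fit(xtr, ytr, xte)
      mean(svm_predict(w$train, ytr, w$test, params$cost) == yte)
    }, 0)
    if (length(accs) == 0) stop("no test variations present in data")
    mean(accs)
  }
}

## condition_id -> category / variation under the canonical 125-condition
## vocabulary (category blocks of 25, identity blocks of 5).
condition_category <- function(condition_id) {
  nf_categories[(condition_id - 1L) %/% 25L + 1L]
}

condition_variation <- function(condition_id) {
  nf_variations[(condition_id - 1L) %% 5L + 1L]
}

#' Aggregate decoding accuracies
#'
#' @param result A `decoding_result`.
#' @return `group_accuracy`: mean accuracy over participants and categories
#'   (vector over time); `category_accuracy`: mean over participants
#'   (`[time x category]` matrix); `participant_accuracy`: mean over
#'   categories (`[participant x time]` matrix).
#' @export
group_accuracy <- function(result) {
  apply(result$accuracy, 3, mean)
}

#' @rdname group_accuracy
#' @export
category_accuracy <- function(result) {
  out <- t(apply(result$accuracy, c(2, 3), mean))
  colnames(out) <- result$categories
  out
}

#' @rdname group_accuracy
#' @export
participant_accuracy <- function(result) {
  apply(result$accuracy, c(1, 3), mean)
}

#' @export
print.decoding_result <- function(x, ...) {
  d <- dim(x$accuracy)
  cat(sprintf("<decoding_result> scheme=%s: %d participant(s) x %d categories x %d timepoint(s); mean accuracy %.3f\n",
              x$scheme, d[1], d[2], d[3], mean(x$accuracy)))
  invisible(x)
}
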