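# Dynamic-feature extraction from trajectories/segments, a simple
# cross-validated classifier of formative division, and single-feature
# discrimination ranking.

#' Extract dynamic features from a trajectory or cell-cycle segment
#'
#' Per channel: maximum and mean level, trapezoidal area under the curve
#' (units x h), maximum rate (first difference of the smoothed series per
#' hour), time to half-maximum (interpolated), and the channel maximum
#' within each nuclear-size quarter (requires `norm_size`; an unvisited
#' quarter yields `NA`, flagged missing rather than silently zero). Unit-level
#' features: initial nuclear size and observed duration.
#'
#' @param unit A [cell_trajectory()] or `cell_cycle_segment`.
#' @param channels Character subset of `c("shr", "scr")`.
#' @param smooth_window Window (frames) for the rate feature, default 5.
#' @return Named list of scalar features (`NA` = missing).
#' @export
extract_features <- function(unit, channels = "shr", smooth_window = 5L) {
  tt <- unit$times
  assert_that(length(tt) >= 1, "unit has an empty series")
  out <- list()
  for (ch in channels) {
    v <- unit_channel(unit, ch)
    assert_that(length(v) >= 1, sprintf("channel '%s' is empty", ch))
    sm <- smooth_series(v, min(smooth_window,
                               if (length(v) %% 2 == 0) length(v) - 1 else length(v)))
    rate <- if (length(v) >= 2) max(diff(sm) / diff(tt)) else NA_real_
    half <- max(v) / 2
    out[[paste0(ch, "_max_level")]] <- max(v)
    out[[paste0(ch, "_mean_level")]] <- mean(v)
    out[[paste0(ch, "_auc")]] <- trapz(tt, v)
    out[[paste0(ch, "_max_rate")]] <- rate
    out[[paste0(ch, "_time_to_half_max")]] <-
      first_crossing_time(tt, v, half) - tt[1L]
    if (!is.null(unit$norm_size)) {
      for (k in 1:4) {
        sel <- in_quarter(unit$norm_size, k)
        out[[paste0(ch, "_max_in_q", k)]] <-
          if (any(sel)) max(v[sel]) else NA_real_
      }
    }
  }
  size <- unit$nuclear_size
  out$initial_nuclear_size <- if (is.null(size)) NA_real_ else size[1L]
  out$duration <- tt[length(tt)] - tt[1L]
  out
}

#' Build a feature table from a list of units
#'
#' @param units List of trajectories or segments.
#' @param channels Channels passed to [extract_features()].
#' @param positive Label treated as the positive class.
#' @param ... Passed to [extract_features()].
#' @return Data frame of features plus a logical `label` column
#'   (`TRUE` = positive class).
#' @export
feature_table <- function(units, channels = "shr", positive = "formative",
                          ...) {
  rows <- lapply(units, function(u) {
    as.data.frame(extract_features(u, channels = channels, ...))
  })
  tab <- do.call(rbind, rows)
  tab$label <- vapply(units, unit_label, "") == positive
  tab
}

stratified_folds <- function(labels, k, seed) {
  assert_that(min(table(labels)) >= k,
              "each class needs at least as many units as folds",
              "shrscr_stratification_error")
  fold <- integer(length(labels))
  set.seed(seed)
  for (cls in unique(labels)) {
    idx <- which(labels == cls)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' Cross-validated classification of formative division
#'
#' Stratified k-fold cross-validation of an L2-regularized logistic
#' classifier (ridge penalty, fixed small lambda) on a feature table.
#' Missing feature values are imputed by the training-fold median and
#' features are standardized by training-fold statistics; both are applied
#' to the held-out fold. Fold assignment is reproducible from `seed` and
#' stratified by label only, so permuting row order does not change the
#' cross-validated accuracy.
#'
#' @param features Data frame of numeric features with a logical `label`
#'   column (as from [feature_table()]).
#' @param folds Number of folds, default 5.
#' @param seed Integer seed for the fold assignment.
#' @param lambda Ridge penalty, default 0.01.
#' @return A `classifier_report`: `cv_accuracy`, `per_fold`, `model_kind`,
#'   `seed`, `n`.
#' @export
train_classifier <- function(features, folds = 5L, seed = 1L, lambda = 0.01) {
  assert_that("label" %in% names(features), "feature table needs a 'label' column")
  y <- features$label
  X <- as.matrix(features[setdiff(names(features), "label")])
  assert_that(nrow(X) >= 2 * folds, "need at least 2 x folds labelled units")
  # order-invariant fold assignment: stratify over rows sorted by a stable key
  key <- order(apply(cbind(X, y), 1L, function(r)
    paste(format(r, digits = 15), collapse = ",")))
  fold_sorted <- stratified_folds(y[key], folds, seed)
  fold <- integer(length(y)); fold[key] <- fold_sorted
  per_fold <- vapply(seq_len(folds), function(f) {
    tr <- fold != f; te <- fold == f
    med <- apply(X[tr, , drop = FALSE], 2L, stats::median, na.rm = TRUE)
    med[!is.finite(med)] <- 0
    impute <- function(M) {
      for (j in seq_len(ncol(M))) M[!is.finite(M[, j]), j] <- med[j]
      M
    }
    Xtr <- impute(X[tr, , drop = FALSE]); Xte <- impute(X[te, , drop = FALSE])
    mu <- colMeans(Xtr); sdv <- apply(Xtr, 2L, stats::sd)
    sdv[sdv == 0 | !is.finite(sdv)] <- 1
    Xtr <- scale(Xtr, mu, sdv); Xte <- scale(Xte, mu, sdv)
    fitted <- glmnet::glmnet(Xtr, factor(y[tr], levels = c(FALSE, TRUE)),
                             family = "binomial", alpha = 0, lambda = lambda,
                             standardize = FALSE)
    p_hat <- as.numeric(stats::predict(fitted, newx = Xte, type = "response"))
    mean((p_hat >= 0.5) == y[te])
  }, numeric(1))
  structure(list(cv_accuracy = mean(per_fold), per_fold = per_fold,
                 model_kind = sprintf("ridge logistic (lambda = %g)", lambda),
                 seed = seed, n = nrow(X)),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("<classifier_report %s: cv accuracy %.3f over %d folds (n = %d)>\n",
              x$model_kind, x$cv_accuracy, length(x$per_fold), x$n))
  invisible(x)
}

#' Rank single features by threshold discrimination
#'
#' For each feature, scans thresholds at the midpoints of its sorted unique
#' values in both orientations of the inequality and records the best
#' accuracy with a one-tailed binomial p-value against chance. Units with a
#' missing value of a feature are dropped for that feature (their count is
#' reported). A constant feature is flagged uninformative; its accuracy is
#' the larger class prevalence.
#'
#' @param features Data frame with a logical `label` column.
#' @return Data frame ranked by decreasing accuracy: `feature`, `accuracy`,
#'   `direction`, `threshold`, `n_used`, `p_binomial`, `uninformative`.
#' @export
single_feature_discrimination <- function(features) {
  y_all <- features$label
  nm <- setdiff(names(features), "label")
  rows <- lapply(nm, function(f) {
    v <- features[[f]]
    keep <- is.finite(v)
    v <- v[keep]; y <- y_all[keep]
    prev <- max(mean(y), 1 - mean(y))
    if (length(unique(v)) <= 1L) {
      return(data.frame(feature = f, accuracy = prev, direction = "none",
                        threshold = NA_real_, n_used = length(v),
                        p_binomial = binomial_one_tailed(round(prev * length(v)),
                                                         length(v)),
                        uninformative = TRUE, stringsAsFactors = FALSE))
    }
    u <- sort(unique(v))
    cuts <- c(u[1L] - 1, (u[-1L] + u[-length(u)]) / 2, u[length(u)] + 1)
    best <- list(acc = -1)
    for (cut in cuts) {
      acc_ge <- mean((v >= cut) == y)
      acc_le <- mean((v <= cut) == y)
      if (acc_ge > best$acc) best <- list(acc = acc_ge, dir = ">=", cut = cut)
      if (acc_le > best$acc) best <- list(acc = acc_le, dir = "<=", cut = cut)
    }
    data.frame(feature = f, accuracy = best$acc, direction = best$dir,
               threshold = best$cut, n_used = length(v),
               p_binomial = binomial_one_tailed(round(best$acc * length(v)),
                                                length(v)),
               uninformative = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$accuracy, out$feature), , drop = FALSE]
}
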