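# Threshold classification of division outcome and the accompanying
# statistics: binomial tail tests, Mann-Whitney comparison of initial
# nuclear sizes, per-treatment first-division summaries, and the G1 /
# nuclear-size concordance.

unit_channel <- function(unit, channel) {
  v <- unit[[channel]]
  if (is.null(v)) {
    abort_shrscr(sprintf("unit '%s' lacks channel '%s'",
                         unit$cell_id %||% "?", channel),
                 "shrscr_feature_unavailable_error")
  }
  v
}

unit_label <- function(unit) {
  if (!is.null(unit$outcome)) return(unit$outcome)
  if (nrow(unit$divisions) && any(unit$divisions$orientation == "formative")) {
    "formative"
  } else if (unit$censored) "censored" else "proliferative"
}

#' Select and label units for a whole-trajectory threshold scan
#'
#' Whole-trajectory scans classify formatively dividing against non-dividing
#' cells: trajectories ending in a formative division keep that label, and
#' cells observed at least `min_duration` hours without any division are
#' labelled non-dividing (retaining the `"censored"` outcome tag).
#' Trajectories that divided only proliferatively, or censored cells observed
#' too briefly, are excluded.
#'
#' @param trajs List of [cell_trajectory()] objects.
#' @param min_duration Minimum observed duration for a non-dividing label,
#'   default 12 h (about one median cell cycle).
#' @return Filtered list of trajectories, each with an `outcome` field set.
#' @export
whole_trajectory_units <- function(trajs, min_duration = 12) {
  out <- list()
  for (tr in trajs) {
    duration <- diff(range(tr$times))
    if (nrow(tr$divisions) && any(tr$divisions$orientation == "formative")) {
      tr$outcome <- "formative"
    } else if (nrow(tr$divisions) == 0L && duration >= min_duration) {
      tr$outcome <- "censored"
    } else next
    out[[length(out) + 1L]] <- tr
  }
  out
}

#' Pool labelled cell-cycle segments from many trajectories
#'
#' Runs [segment_cycles()] on every trajectory carrying nuclear size and
#' keeps segments with the requested outcomes (by default the formative vs
#' proliferative universe of per-cycle windowed scans).
#'
#' @param trajs List of [cell_trajectory()] objects.
#' @param outcomes Outcome labels to keep.
#' @return Flat list of `cell_cycle_segment`s.
#' @export
collect_segments <- function(trajs, outcomes = c("formative", "proliferative")) {
  segs <- unlist(lapply(trajs, function(tr) {
    if (is.null(tr$nuclear_size)) return(NULL)
    segment_cycles(tr)
  }), recursive = FALSE)
  segs[vapply(segs, function(s) s$outcome %in% outcomes, TRUE)]
}

#' Quarter membership of normalized nuclear sizes
#'
#' Quarters are half-open `[(k-1)/4, k/4)` except the last, which is closed
#' at 1; a boundary value belongs to the higher quarter's left edge.
#' @noRd
in_quarter <- function(norm_size, k) {
  lo <- (k - 1) / 4; hi <- k / 4
  if (k == 4L) norm_size >= lo & norm_size <= hi else norm_size >= lo & norm_size < hi
}

#' Classify units as formative by a channel threshold
#'
#' A unit is predicted formative when the channel reaches at least `theta`
#' at one or more timepoints; with `window = k`, only timepoints whose
#' per-cycle normalized nuclear size lies in quarter `k` count.
#'
#' @param units List of trajectories or cell-cycle segments.
#' @param channel `"shr"` or `"scr"`.
#' @param theta Threshold in normalized units.
#' @param window Optional nuclear-size quarter 1-4.
#' @return Logical vector, `TRUE` = predicted formative.
#' @export
classify_by_threshold <- function(units, channel = c("shr", "scr"), theta,
                                  window = NULL) {
  channel <- match.arg(channel)
  vapply(units, function(u) {
    v <- unit_channel(u, channel)
    if (!is.null(window)) {
      if (is.null(u$norm_size)) {
        abort_shrscr("windowed classification needs segments with norm_size",
                     "shrscr_feature_unavailable_error")
      }
      v <- v[in_quarter(u$norm_size, window)]
    }
    length(v) > 0 && any(v >= theta, na.rm = TRUE)
  }, TRUE)
}

#' Exact one-tailed binomial test against chance
#'
#' Upper-tail probability \eqn{P(X \ge k)} for \eqn{X \sim Bin(n, p_0)}.
#' @param k Successes. @param n Trials. @param p0 Chance probability.
#' @return Exact p-value.
#' @export
binomial_one_tailed <- function(k, n, p0 = 0.5) {
  assert_that(length(k) == 1 && length(n) == 1 && k >= 0 && n >= 1 && k <= n &&
                k == round(k) && n == round(n),
              "'k' and 'n' must be integers with 0 <= k <= n")
  stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
}

#' Scan a threshold grid for classification accuracy
#'
#' For every threshold on the grid, units are classified by
#' [classify_by_threshold()] and accuracy is the fraction matching the true
#' labels. Two class universes are supported and selected by the labels the
#' units carry: whole-trajectory scans score formative against non-dividing
#' (censored) cells; per-cycle windowed scans score formative against
#' proliferative segments. Ties in accuracy are broken toward the smallest
#' threshold.
#'
#' @param units Labelled trajectories or segments; both classes must occur.
#' @param channel `"shr"` or `"scr"`.
#' @param grid Ascending thresholds; default 200 evenly spaced values from 0
#'   to the 99th percentile of the channel's values across units.
#' @param window Optional nuclear-size quarter.
#' @param positive Label counted as the positive class, default
#'   `"formative"`.
#' @return A `threshold_scan_result`: list with the grid, per-threshold
#'   accuracy, `best_theta`, `best_accuracy`, `n`, the one-tailed binomial
#'   p-value of the best accuracy against 0.5, `window` and `channel`.
#' @export
threshold_scan <- function(units, channel = c("shr", "scr"), grid = NULL,
                           window = NULL, positive = "formative") {
  channel <- match.arg(channel)
  labels <- vapply(units, unit_label, "")
  truth <- labels == positive
  if (length(unique(truth)) < 2L) {
    abort_shrscr("threshold scan needs units of both classes",
                 "shrscr_degenerate_scan_error")
  }
  if (is.null(grid)) {
    pooled <- unlist(lapply(units, unit_channel, channel))
    grid <- seq(0, stats::quantile(pooled, 0.99, type = 7, na.rm = TRUE),
                length.out = 200L)
  }
  assert_that(!is.unsorted(grid), "'grid' must be ascending")
  acc <- vapply(grid, function(theta) {
    pred <- classify_by_threshold(units, channel, theta, window)
    mean(pred == truth)
  }, numeric(1))
  best_i <- which.max(acc)   # which.max returns the first (smallest) maximum
  n <- length(units)
  structure(
    list(channel = channel, grid = grid, accuracy = acc,
         best_theta = grid[best_i], best_accuracy = acc[best_i],
         window = window, n = n,
         p_binomial = binomial_one_tailed(round(acc[best_i] * n), n, 0.5)),
    class = "threshold_scan_result")
}

#' @export
print.threshold_scan_result <- function(x, ...) {
  cat(sprintf("<threshold_scan %s%s: best accuracy %.3f at theta = %.4g (n = %d, p = %.3g)>\n",
              toupper(x$channel),
              if (!is.null(x$window)) sprintf(" Q%d", x$window) else "",
              x$best_accuracy, x$best_theta, x$n, x$p_binomial))
  invisible(x)
}

#' Windowed threshold scans over all four nuclear-size quarters
#'
#' Runs [threshold_scan()] restricted to each quarter of the per-cycle
#' normalized nuclear-size range. Whether quarter 1 comes out most accurate
#' is a property of the data, not of this function.
#'
#' @inheritParams threshold_scan
#' @param segments Cell-cycle segments (formative vs proliferative labels).
#' @return Named list of four `threshold_scan_result`s (`Q1` .. `Q4`).
#' @export
windowed_scan_all_quarters <- function(segments, channel = c("shr", "scr"),
                                       grid = NULL) {
  channel <- match.arg(channel)
  out <- lapply(1:4, function(k) threshold_scan(segments, channel, grid,
                                                window = k))
  names(out) <- paste0("Q", 1:4)
  out
}

#' Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Exact p-value by full enumeration of group assignments for combined
#' sample sizes up to `exact_max` (ties handled naturally by enumeration);
#' tie-corrected normal approximation above. The U statistic reported is for
#' the first sample.
#'
#' @param x,y Numeric samples.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @param exact_max Combined size at or below which the exact null
#'   distribution is enumerated (default 20).
#' @return List with `U`, `p_value`, `method`, medians and IQRs.
#' @export
mann_whitney <- function(x, y, alternative = c("two.sided", "less", "greater"),
                         exact_max = 20L) {
  alternative <- match.arg(alternative)
  assert_that(length(x) >= 1 && length(y) >= 1, "both groups must be non-empty")
  m <- length(x); n <- length(y)
  u_stat <- function(ranks_x) sum(ranks_x) - m * (m + 1) / 2
  r_all <- rank(c(x, y))
  U <- u_stat(r_all[seq_len(m)])
  if (m + n <= exact_max) {
    combos <- utils::combn(m + n, m)
    U_null <- apply(combos, 2L, function(idx) u_stat(r_all[idx]))
    p_le <- mean(U_null <= U); p_ge <- mean(U_null >= U)
    p <- switch(alternative,
                two.sided = min(1, 2 * min(p_le, p_ge)),
                less = p_le, greater = p_ge)
    method <- "exact enumeration"
  } else {
    mu <- m * n / 2
    ties <- table(r_all)
    tie_term <- sum(ties^3 - ties) / ((m + n) * (m + n - 1))
    sigma <- sqrt(m * n / 12 * ((m + n + 1) - tie_term))
    # continuity-corrected normal approximation
    z_less <- (U + 0.5 - mu) / sigma
    z_greater <- (U - 0.5 - mu) / sigma
    p <- switch(alternative,
                two.sided = min(1, 2 * min(stats::pnorm(z_less),
                                           stats::pnorm(z_greater,
                                                        lower.tail = FALSE))),
                less = stats::pnorm(z_less),
                greater = stats::pnorm(z_greater, lower.tail = FALSE))
    method <- "tie-corrected normal approximation"
  }
  list(U = U, p_value = p, method = method,
       median_x = stats::median(x), median_y = stats::median(y),
       iqr_x = unname(stats::quantile(x, c(0.25, 0.75), type = 7)),
       iqr_y = unname(stats::quantile(y, c(0.25, 0.75), type = 7)))
}

#' Compare initial nuclear sizes of formative vs proliferative cells
#'
#' The initial size of each unit is its first normalized nuclear-size value;
#' groups are compared by a two-tailed Mann-Whitney test. Proliferatively
#' dividing cells that were already past the early cell-cycle window at
#' induction are expected to start larger.
#'
#' @param formative,proliferative Numeric vectors of initial normalized
#'   sizes (e.g. from [initial_norm_size()]).
#' @return The [mann_whitney()] report.
#' @export
initial_size_comparison <- function(formative, proliferative) {
  mann_whitney(formative, proliferative, alternative = "two.sided")
}

#' Per-treatment summary of first divisions after induction
#'
#' Computes, per root, the percentage of first divisions that were formative;
#' summarizes each treatment as mean +/- s.e.m. over roots; and compares each
#' non-control treatment with the control by a classic (equal-variance)
#' two-sample one-sided Student's t-test on the per-root percentages. When
#' both groups have zero within-group variance the t statistic is degenerate
#' and the p-value is reported as 0 with `degenerate = TRUE`.
#'
#' @param table Data frame with columns `root_id`, `treatment`, `cell_id`,
#'   `orientation` (one first-division record per cell).
#' @param control Treatment level acting as reference, default `"control"`.
#' @param alternative Direction of each comparison (alternative hypothesis
#'   for treatment vs control), default `"greater"`; may be a named vector
#'   keyed by treatment.
#' @return List with `per_root` (root-level percentages), `summary`
#'   (per-treatment mean, sem, n_roots) and `tests` (one row per non-control
#'   treatment).
#' @export
first_division_summary <- function(table, control = "control",
                                   alternative = "greater") {
  assert_that(all(c("root_id", "treatment", "cell_id", "orientation") %in%
                    names(table)),
              "division table needs root_id, treatment, cell_id, orientation")
  assert_that(!anyDuplicated(paste(table$root_id, table$cell_id)),
              "one first-division record per cell expected")
  per_root <- do.call(rbind, lapply(split(table, table$root_id), function(g) {
    assert_that(length(unique(g$treatment)) == 1L,
                "treatment must be uniform within a root")
    data.frame(root_id = g$root_id[1L], treatment = g$treatment[1L],
               n_firsts = nrow(g),
               pct_formative = 100 * mean(g$orientation == "formative"),
               stringsAsFactors = FALSE)
  }))
  rownames(per_root) <- NULL
  summary <- do.call(rbind, lapply(split(per_root, per_root$treatment),
                                   function(g) {
    data.frame(treatment = g$treatment[1L], n_roots = nrow(g),
               mean_pct = mean(g$pct_formative),
               sem_pct = standard_error(g$pct_formative),
               stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  assert_that(control %in% per_root$treatment,
              sprintf("control treatment '%s' has zero roots", control))
  ctrl <- per_root$pct_formative[per_root$treatment == control]
  others <- setdiff(unique(per_root$treatment), control)
  tests <- do.call(rbind, lapply(others, function(tr) {
    alt <- if (length(alternative) > 1L) alternative[[tr]] else alternative
    trt <- per_root$pct_formative[per_root$treatment == tr]
    degenerate <- stats::sd(trt) == 0 && stats::sd(ctrl) == 0
    if (degenerate) {
      p <- if (mean(trt) == mean(ctrl)) 1 else 0
      tval <- if (mean(trt) == mean(ctrl)) 0 else sign(mean(trt) - mean(ctrl)) * Inf
    } else {
      ht <- stats::t.test(trt, ctrl, alternative = alt, var.equal = TRUE)
      p <- ht$p.value; tval <- unname(ht$statistic)
    }
    data.frame(treatment = tr, control = control, alternative = alt,
               t = tval, p_value = p, degenerate = degenerate,
               stringsAsFactors = FALSE)
  }))
  list(per_root = per_root, summary = summary, tests = tests)
}

#' Concordance of the nuclear-size quartile crossing with G1
#'
#' For each complete cell cycle, finds the first (linearly interpolated) time
#' the nuclear size crosses the 25th percentile of its within-cycle range
#' (normalized size 0.25) and scores a success when that time falls within G1
#' or at most `grace_h` hours after G1 ends (closed boundary). Cycles without
#' any G1-on interval are excluded and counted.
#'
#' @param cycles List of cycles, each a list with `times`, `g1_on` (logical),
#'   `size`, and optionally `root_id`.
#' @param grace_h Grace period after G1 end, default 1 h.
#' @return List with `fraction` (mean success over roots), `sem` (over
#'   roots), `n_cycles`, `n_excluded`, and `per_root`.
#' @export
g1_window_concordance <- function(cycles, grace_h = 1) {
  res <- lapply(cycles, function(cy) {
    if (!any(cy$g1_on)) return(NULL)
    rng <- range(cy$size)
    if (diff(rng) == 0) return(NULL)
    norm <- (cy$size - rng[1L]) / diff(rng)
    t_cross <- first_crossing_time(cy$times, norm, 0.25)
    g1_end <- max(cy$times[cy$g1_on])
    data.frame(root_id = cy$root_id %||% "root",
               success = !is.na(t_cross) && t_cross <= g1_end + grace_h)
  })
  excluded <- sum(vapply(res, is.null, TRUE))
  res <- do.call(rbind, res)
  assert_that(!is.null(res) && nrow(res) > 0, "no cycle with a G1 interval")
  per_root <- vapply(split(res$success, res$root_id), mean, numeric(1))
  list(fraction = mean(per_root),
       sem = standard_error(per_root),
       n_cycles = nrow(res), n_excluded = excluded,
       per_root = per_root)
}

#' Export a threshold scan as CSV (theta, accuracy) plus a JSON summary
#' @param scan A `threshold_scan_result`.
#' @param csv_path,json_path Output paths (either may be `NULL`).
#' @return Invisibly, the paths written.
#' @export
write_scan_results <- function(scan, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) {
    utils::write.csv(data.frame(theta = scan$grid, accuracy = scan$accuracy),
                     csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(channel = scan$channel, window = scan$window,
           best_theta = scan$best_theta, best_accuracy = scan$best_accuracy,
           n = scan$n, p_binomial = scan$p_binomial),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(c(csv_path, json_path))
}
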