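test_that("threshold classification behaves at the extremes and on separable toys", {
  units <- toy_units(
    values_formative = list(c(0.1, 0.8, 0.2), c(0.2, 0.8, 0.3)),
    values_other = list(c(0.1, 0.2, 0.1), c(0.05, 0.2, 0.15)))
  expect_true(all(classify_by_threshold(units, "shr", 0)))
  expect_false(any(classify_by_threshold(units, "shr", 10)))
  pred <- classify_by_threshold(units, "shr", 0.5)
  truth <- vapply(units, function(u) u$outcome == "formative", TRUE)
  expect_equal(mean(pred == truth), 1)
})

test_that("threshold_scan finds the separating threshold and matches brute force", {
  units <- toy_units(
    values_formative = list(c(0.1, 0.8, 0.2), c(0.2, 0.8, 0.3)),
    values_other = list(c(0.1, 0.2, 0.1), c(0.05, 0.2, 0.15)))
  scan <- threshold_scan(units, "shr", grid = seq(0, 1, by = 0.05))
  expect_equal(scan$best_accuracy, 1)
  expect_equal(scan$best_theta, 0.25)  # smallest separating theta on the grid
  expect_equal(scan$n, 4L)

  # brute-force confusion counts on a random unit set
  set.seed(42)
  vals <- lapply(1:50, function(i) runif(8))
  labs <- sample(c("formative", "censored"), 50, replace = TRUE)
  units50 <- toy_units(vals[labs == "formative"], vals[labs == "censored"])
  grid <- seq(0, 1, by = 0.1)
  scan50 <- threshold_scan(units50, "shr", grid = grid)
  for (i in seq_along(grid)) {
    correct <- 0
    for (u in units50) {
      pred <- any(u$shr >= grid[i])
      correct <- correct + (pred == (u$outcome == "formative"))
    }
    expect_equal(scan50$accuracy[i], correct / 50)
  }
  # predicted-positive count is non-increasing in theta
  pos <- vapply(grid, function(th)
    sum(classify_by_threshold(units50, "shr", th)), 1)
  expect_true(all(diff(pos) <= 0))
  # accuracy at theta=0 is formative prevalence
  prev <- mean(labs == "formative")
  expect_equal(scan50$accuracy[1], prev)
  expect_error(threshold_scan(units50[seq_len(sum(labs == "formative"))], "shr"),
               class = "shrscr_degenerate_scan_error")
})

test_that("windowed scans restrict to nuclear-size quarters", {
  # values rise with norm_size; a window keeps only its quarter's values
  u <- toy_units(list(seq(0, 1, length.out = 9)), list(rep(0.05, 9)))
  expect_true(classify_by_threshold(u, "shr", 0.1, window = 2)[1])
  expect_false(classify_by_threshold(u, "shr", 0.9, window = 2)[1])
  # boundary values belong to the higher quarter's left edge
  u2 <- toy_units(list(c(0, 1)), list(c(0, 0)))  # norm_size 0, 1
  expect_false(classify_by_threshold(u2, "shr", 0.5, window = 1)[1]) # value 0 at size 0
  expect_true(classify_by_threshold(u2, "shr", 0.5, window = 4)[1])  # size 1 closed
  # units never entering a quarter predict nothing positive there
  flat <- toy_units(list(c(0.9, 0.9)), list(c(0.9, 0.9)))
  for (i in seq_along(flat)) flat[[i]]$norm_size <- c(0.1, 0.12)
  expect_false(any(classify_by_threshold(flat, "shr", 0.5, window = 3)))
  no_size <- lapply(flat, function(x) { x$norm_size <- NULL; x })
  expect_error(classify_by_threshold(no_size, "shr", 0.5, window = 1),
               class = "shrscr_feature_unavailable_error")
})

test_that("one-tailed binomial p-values are exact", {
  expect_equal(binomial_one_tailed(3, 3), 0.125)
  expect_equal(binomial_one_tailed(8, 10), 0.0546875)  # (45+10+1)/1024
  expect_equal(binomial_one_tailed(0, 7), 1)
  # exact enumeration for all n <= 12, several p0
  for (p0 in c(0.3, 0.5, 0.7)) {
    for (n in 1:12) {
      for (k in 0:n) {
        enum <- sum(choose(n, k:n) * p0^(k:n) * (1 - p0)^(n - (k:n)))
        expect_equal(binomial_one_tailed(k, n, p0), enum, tolerance = 1e-12)
      }
    }
  }
  expect_error(binomial_one_tailed(5, 3), class = "shrscr_argument_error")
})

test_that("Mann-Whitney matches the reference implementation and enumeration", {
  expect_equal(mann_whitney(1:3, 4:6)$U, 0)
  expect_equal(mann_whitney(1:3, 4:6)$p_value, 0.1)  # 2/20 arrangements
  # tie-free exact cases against stats::wilcox.test
  set.seed(9)
  for (i in 1:10) {
    x <- rnorm(sample(3:5, 1)); y <- rnorm(sample(3:5, 1))
    ours <- mann_whitney(x, y)
    ref <- wilcox.test(x, y, exact = TRUE)
    expect_equal(ours$U, unname(ref$statistic))
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  }
  # identical groups: p of 1 under symmetry
  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  # large-sample path agrees with the corrected normal approximation
  set.seed(10)
  x <- rnorm(15); y <- rnorm(15, 0.5)
  ours <- mann_whitney(x, y)
  ref <- wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(ours$method, "tie-corrected normal approximation")
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-9)
  expect_error(mann_whitney(numeric(0), 1:3), class = "shrscr_argument_error")
})

test_that("initial size comparison reports medians and a two-tailed p", {
  res <- initial_size_comparison(c(0.1, 0.15, 0.2), c(0.6, 0.7, 0.8))
  expect_equal(res$p_value, 0.1)
  expect_lt(res$median_x, res$median_y)
})

test_that("first-division summaries aggregate per root and test against control", {
  tab <- data.frame(
    root_id = rep(c("r1", "r2", "r3", "r4", "r5", "r6"), each = 10),
    treatment = rep(c("control", "hydroxyurea"), each = 30),
    cell_id = paste0("c", 1:60),
    orientation = c(rep(c("formative", "proliferative"), c(5, 5)),
                    rep(c("formative", "proliferative"), c(4, 6)),
                    rep(c("formative", "proliferative"), c(6, 4)),
                    rep(c("formative", "proliferative"), c(10, 0)),
                    rep(c("formative", "proliferative"), c(9, 1)),
                    rep(c("formative", "proliferative"), c(9, 1))),
    stringsAsFactors = FALSE)
  out <- first_division_summary(tab, alternative = "greater")
  expect_equal(sort(out$per_root$pct_formative[out$per_root$treatment == "control"]),
               c(40, 50, 60))
  hu <- out$summary[out$summary$treatment == "hydroxyurea", ]
  expect_equal(hu$mean_pct, mean(c(100, 90, 90)))
  ctrl_t <- t.test(c(100, 90, 90), c(50, 40, 60), alternative = "greater",
                   var.equal = TRUE)
  expect_equal(out$tests$p_value, ctrl_t$p.value)
  # mean +/- sem arithmetic: {100, 90, 92} -> 94 +/- 3.06
  tab2 <- data.frame(
    root_id = rep(c("a", "b", "c", "z"), c(10, 10, 25, 2)),
    treatment = rep(c("hydroxyurea", "control"), c(45, 2)),
    cell_id = paste0("c", 1:47),
    orientation = c(rep(c("formative", "proliferative"), c(10, 0)),
                    rep(c("formative", "proliferative"), c(9, 1)),
                    rep(c("formative", "proliferative"), c(23, 2)),
                    "proliferative", "proliferative"),
    stringsAsFactors = FALSE)
  s2 <- first_division_summary(tab2)
  hu2 <- s2$summary[s2$summary$treatment == "hydroxyurea", ]
  expect_equal(hu2$mean_pct, 94)
  expect_equal(hu2$sem_pct, sd(c(100, 90, 92)) / sqrt(3))
  # degenerate zero-variance comparison is flagged
  tab3 <- data.frame(
    root_id = rep(c("r1", "r2", "r3", "r4"), each = 3),
    treatment = rep(c("control", "oryzalin"), each = 6),
    cell_id = paste0("c", 1:12),
    orientation = rep(c("formative", "proliferative"), each = 6),
    stringsAsFactors = FALSE)
  s3 <- first_division_summary(tab3, alternative = "less")
  expect_true(s3$tests$degenerate)
  expect_equal(s3$tests$p_value, 0)
})

test_that("G1 concordance scores interpolated quartile crossings", {
  # G1 spanning the whole cycle -> success regardless of crossing time
  full <- list(list(times = 0:10, g1_on = rep(TRUE, 11), size = seq(40, 110, 7),
                    root_id = "r1"))
  expect_equal(g1_window_concordance(full)$fraction, 1)
  # crossing exactly at G1 end + 1 h counts (closed boundary)
  tt <- seq(0, 10, by = 0.5)
  size <- 40 + 70 * tt / 10          # crosses norm 0.25 at t = 2.5
  edge <- list(list(times = tt, g1_on = tt <= 1.5, size = size, root_id = "r"))
  expect_equal(g1_window_concordance(edge)$fraction, 1)
  late <- list(list(times = tt, g1_on = tt <= 1.4, size = size, root_id = "r"))
  expect_equal(g1_window_concordance(late)$fraction, 0)
  # cycles without G1 are excluded and counted
  mix <- c(full, list(list(times = tt, g1_on = rep(FALSE, 21), size = size,
                           root_id = "r2")))
  out <- g1_window_concordance(mix)
  expect_equal(out$n_excluded, 1L)
  expect_equal(out$n_cycles, 1L)
})
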