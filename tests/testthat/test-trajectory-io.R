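test_that("load_trajectories reads, groups and validates long-format tables", {
  path <- write_toy_csv()
  trajs <- load_trajectories(path)
  expect_length(trajs, 2L)
  expect_equal(vapply(trajs, function(t) length(t$times), 1L),
               c(`r1/a` = 4L, `r1/b` = 4L))
  expect_equal(trajs[["r1/b"]]$shr, c(1, 2, 3, 4))

  # 15-min spacing over 24 h -> 97 timepoints
  tt <- seq(0, 24, by = 0.25)
  tab <- data.frame(root_id = "r", cell_id = "c", time_h = tt,
                    shr = seq_along(tt))
  p2 <- tempfile(fileext = ".csv")
  utils::write.csv(tab, p2, row.names = FALSE)
  expect_length(load_trajectories(p2)[[1]]$times, 97L)
})

test_that("load_trajectories rejects bad input with informative errors", {
  expect_error(load_trajectories(write_toy_csv(duplicate_row = TRUE)),
               class = "shrscr_validation_error")
  expect_error(load_trajectories(write_toy_csv(negative = TRUE)),
               class = "shrscr_validation_error")
  path <- write_toy_csv()
  expect_error(
    load_trajectories(path, trajectory_schema(shr = "not_a_column")),
    regexp = "not_a_column", class = "shrscr_schema_error")
  expect_error(load_trajectories(tempfile()), class = "shrscr_path_error")
})

test_that("trajectory round-trips through the canonical CSV", {
  tr <- toy_trajectory()
  path <- tempfile(fileext = ".csv")
  write_trajectories_csv(list(tr), path)
  back <- load_trajectories(path)[[1]]
  expect_equal(back$times, tr$times)
  expect_equal(back$shr, tr$shr)
  expect_equal(back$divisions$orientation, tr$divisions$orientation)
})

test_that("smoothing is a shrinking-window moving average", {
  expect_equal(smooth_series(c(0, 3, 0), 3), c(1.5, 1, 1.5))
  x <- rnorm(20)
  expect_equal(smooth_series(x, 1), x)                  # identity window
  expect_equal(smooth_series(rep(2.5, 9), 5), rep(2.5, 9))
  expect_error(smooth_series(x, 4), class = "shrscr_argument_error")
  expect_error(smooth_series(x, 0), class = "shrscr_argument_error")
  # commutes with constant shifts; full-length window preserves the mean
  expect_equal(smooth_series(x + 7, 5), smooth_series(x, 5) + 7)
  n <- 11
  expect_equal(smooth_series(x[1:n], n)[(n + 1) / 2], mean(x[1:n]))
})

test_that("quantile normalization uses the interpolated quantile and is scale-equivariant", {
  out <- normalize_to_quantile(1:10, q = 0.9)
  expect_equal(out, (1:10) / 9.1)   # 0.9*(10-1)+1 = 9.1th order statistic
  expect_equal(normalize_to_quantile(rep(3, 5)), rep(1, 5))
  # q-quantile of self-normalized output is 1
  x <- rlnorm(50)
  expect_equal(unname(quantile(normalize_to_quantile(x), 0.9, type = 7)), 1)
  # scale equivariance
  expect_equal(normalize_to_quantile(5 * x), normalize_to_quantile(x))
  expect_error(normalize_to_quantile(rep(0, 5)),
               class = "shrscr_degenerate_normalization_error")
})

test_that("averaging respects coverage and reports sem", {
  grid <- seq(0, 1, by = 0.25)
  s <- list(times = grid, values = grid * 2)
  avg <- average_trajectories(list(s, s, s), grid)
  expect_equal(avg$mean, grid * 2)
  expect_equal(avg$sem, rep(0, 5))
  expect_equal(avg$n, rep(3L, 5))

  two <- list(list(times = grid, values = rep(0, 5)),
              list(times = grid, values = rep(2, 5)))
  avg2 <- average_trajectories(two, grid)
  expect_equal(avg2$mean, rep(1, 5))    # sd = sqrt(2), sem = sqrt(2)/sqrt(2)
  expect_equal(avg2$sem, rep(1, 5))

  # a cell ending early stops contributing: n_at_t non-increasing afterwards
  short <- list(times = grid[1:3], values = rep(1, 3))
  avg3 <- average_trajectories(list(s, short), grid)
  expect_equal(avg3$n, c(2, 2, 2, 1, 1))
  expect_error(average_trajectories(list(), grid),
               class = "shrscr_argument_error")
  expect_warning(
    average_trajectories(list(short), grid),
    regexp = "covered by no cell")
})

test_that("cycle segmentation partitions the span and labels outcomes", {
  tr <- toy_trajectory()
  segs <- segment_cycles(tr)
  expect_length(segs, 2L)
  expect_equal(vapply(segs, `[[`, "", "outcome"),
               c("proliferative", "formative"))
  # partition: spans abut and cover the trajectory
  expect_equal(segs[[1]]$span, c(0, 5))
  expect_equal(segs[[2]]$span, c(5, 12))
  # norm_size spans [0,1] in every segment with >= 2 distinct sizes
  for (s in segs) expect_equal(range(s$norm_size), c(0, 1))

  # hand-checked min-max rescale
  tt <- c(0, 1, 2, 3)
  tr2 <- cell_trajectory("c", "r", tt, shr = rep(1, 4),
                         nuclear_size = c(10, 12, 14, 20))
  expect_equal(segment_cycles(tr2)[[1]]$norm_size, c(0, 0.2, 0.4, 1))

  # censored, undivided cell -> one censored segment
  tr3 <- cell_trajectory("c", "r", tt, shr = rep(1, 4),
                         nuclear_size = c(10, 12, 14, 20))
  expect_equal(segment_cycles(tr3)[[1]]$outcome, "censored")
  tr4 <- cell_trajectory("c", "r", tt, shr = rep(1, 4))
  expect_error(segment_cycles(tr4), class = "shrscr_feature_unavailable_error")
})

test_that("trajectory validation enforces the container invariants", {
  expect_error(cell_trajectory("c", "r", c(0, 1, 1), shr = 1:3),
               class = "shrscr_validation_error")
  expect_error(cell_trajectory("c", "r", 0:2, shr = c(1, -1, 1)),
               class = "shrscr_validation_error")
  expect_error(
    cell_trajectory("c", "r", 0:2, shr = 1:3,
                    divisions = data.frame(time = 5, orientation = "formative")),
    class = "shrscr_validation_error")
  expect_error(
    cell_trajectory("c", "r", 0:3, shr = 1:4,
                    divisions = data.frame(time = c(1, 2),
                                           orientation = c("formative",
                                                           "proliferative"))),
    class = "shrscr_validation_error")
})
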