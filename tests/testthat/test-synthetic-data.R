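test_that("generation is deterministic and self-consistent", {
  cfg <- synthetic_config(n_roots = 2, cells_per_root = 10, seed = 4)
  a <- generate_trajectories(cfg)
  b <- generate_trajectories(cfg)
  expect_identical(a, b)
  lab <- vapply(a$ground_truth$cells, `[[`, "", "label")
  expect_identical(replay_decision_rule(a, cfg), lab)
  # trajectories truncate at the formative division
  for (key in names(a$trajectories)) {
    tr <- a$trajectories[[key]]
    if (!tr$censored) {
      expect_equal(max(tr$times), max(tr$divisions$time))
      expect_equal(tr$divisions$orientation[nrow(tr$divisions)], "formative")
    }
  }
})

test_that("dose zero produces no formative divisions and full dose saturates", {
  base <- synthetic_config(n_roots = 3, cells_per_root = 15, seed = 6)
  ds <- generate_dose_series(base, c(0.01, 10))
  expect_equal(formative_fraction(ds[["0.01"]]), 0)
  expect_gt(formative_fraction(ds[["10"]]), 0.9)
  # dose-response monotone over a ladder (single seed, in expectation)
  ds3 <- generate_dose_series(base, c(0.01, 0.1, 10))
  fr <- vapply(ds3, formative_fraction, numeric(1), among = "all")
  expect_true(all(diff(fr) >= 0))
})

test_that("per-dose datasets do not depend on the order of generation", {
  base <- synthetic_config(n_roots = 2, cells_per_root = 8, seed = 11)
  fwd <- generate_dose_series(base, c(0.05, 10))
  rev <- generate_dose_series(base, c(10, 0.05))
  expect_identical(fwd[["10"]], rev[["10"]])
  expect_identical(fwd[["0.05"]], rev[["0.05"]])
})

test_that("config validation rejects out-of-domain settings", {
  expect_error(synthetic_config(censor_frac = 1.2), class = "shrscr_config_error")
  expect_error(synthetic_config(theta_star = -1), class = "shrscr_config_error")
  expect_error(synthetic_config(window_star = 5), class = "shrscr_config_error")
  expect_error(synthetic_config(size_min = 100, size_max = 50),
               class = "shrscr_config_error")
  expect_error(synthetic_config(dt = 0), class = "shrscr_config_error")
})

test_that("dose-amplitude map is monotone non-decreasing", {
  cfg <- synthetic_config()
  doses <- c(0, 0.01, 0.05, 0.2, 1, 5, 10, 40)
  expect_true(all(diff(dose_amplitude(cfg, doses)) >= 0))
})

test_that("cells dividing proliferatively first start larger in the cycle", {
  # fast induction so a well-powered fraction of cells is still inside the
  # early window when the threshold is first reached
  cfg <- ladder_config(seed = 8, onset_delay = 0.5, rise_rate = 1.5)
  res <- generate_trajectories(cfg)
  # group fully induced cells by the orientation of their first division:
  # cells already past the early window at induction divide proliferatively
  # before the eventual formative division
  high <- vapply(res$ground_truth$cells, function(c) c$dex_dose >= 1, TRUE)
  first_div <- vapply(res$trajectories, function(tr) {
    if (nrow(tr$divisions)) tr$divisions$orientation[1] else NA_character_
  }, "")
  phase0 <- vapply(res$ground_truth$cells, function(c) c$phase[1], 0)
  grp_f <- high & !is.na(first_div) & first_div == "formative"
  grp_p <- high & !is.na(first_div) & first_div == "proliferative"
  expect_gt(sum(grp_f), 5); expect_gt(sum(grp_p), 5)
  expect_gt(median(phase0[grp_p]), median(phase0[grp_f]))
  # observable version of the same asymmetry
  init <- vapply(res$trajectories, initial_norm_size, 0)
  mw <- initial_size_comparison(init[grp_f], init[grp_p])
  expect_lt(mw$median_x, mw$median_y)
  expect_lt(mw$p_value, 0.05)
})

test_that("emitted G1 cycles give an enumerable concordance", {
  cfg <- synthetic_config(seed = 5)
  cyc <- emit_cycle_marker_set(cfg, n_cycles = 36)
  out <- g1_window_concordance(cyc)
  # direct enumeration oracle over the same cycles
  succ <- vapply(cyc, function(cy) {
    rng <- range(cy$size)
    norm <- (cy$size - rng[1]) / diff(rng)
    i <- which(norm >= 0.25)[1]
    tc <- if (i == 1) cy$times[1] else {
      v0 <- norm[i - 1]; v1 <- norm[i]
      cy$times[i - 1] + (0.25 - v0) / (v1 - v0) * diff(cy$times[(i - 1):i])
    }
    tc <= max(cy$times[cy$g1_on]) + 1
  }, TRUE)
  roots <- vapply(cyc, `[[`, "", "root_id")
  expect_equal(out$fraction, mean(tapply(succ, roots, mean)))
  # G1 spanning the whole cycle -> concordance 1
  cfg_full <- synthetic_config(seed = 5, g1_fraction = 1, g1_fraction_sd = 0)
  expect_equal(g1_window_concordance(emit_cycle_marker_set(cfg_full, 10))$fraction, 1)
  # no G1 at all and crossing after the grace hour -> concordance 0
  cfg_none <- synthetic_config(seed = 5, g1_fraction = 0.02,
                               g1_fraction_sd = 0)
  expect_lt(g1_window_concordance(emit_cycle_marker_set(cfg_none, 10))$fraction,
            0.2)
})

test_that("synchronized division tables order treatments as expected", {
  tab <- synthesize_division_table(synthetic_config(seed = 2))
  out <- first_division_summary(tab, alternative = c(hydroxyurea = "greater",
                                                     oryzalin = "less"))
  m <- setNames(out$summary$mean_pct, out$summary$treatment)
  expect_gt(m[["hydroxyurea"]], m[["control"]])
  expect_gte(m[["control"]], m[["oryzalin"]])
  expect_lt(out$tests$p_value[out$tests$treatment == "hydroxyurea"], 0.01)
})
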