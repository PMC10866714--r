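# Ground-truth synthetic trajectory generator. Emulates the statistical
# structure of dexamethasone-induced SHR/SCR timecourses: sigmoid SHR
# accumulation with dose-dependent amplitude, SCR driven downstream by an
# ODE, sawtooth nuclear-size growth across lognormal cell cycles sampled
# every 15 min, division outcomes set by a channel threshold met inside an
# early nuclear-size window, arrested (censored) cells, and multiplicative
# measurement noise.

#' Configuration of the synthetic trajectory generator
#'
#' Defaults describe a fully induced (10 uM dex) timecourse: 5 roots x 40
#' cells sampled every 0.25 h for 48 h; SHR rises as a sigmoid (onset delay
#' 3 h, rate 0.4 h^-1) to a dose-dependent plateau (Hill dose map saturating
#' near 1 between 1 and 10 uM and negligible at 0.01 uM); SCR follows the
#' default Michaelis-Menten model; cell-cycle lengths are lognormal with
#' median 12 h; nuclear size grows linearly within each cycle from
#' `size_min` to `size_max` and resets at division. A formative division is
#' planted at the end of a cycle iff the noiseless decision channel reaches
#' `theta_star` at a timepoint whose true cycle phase lies in nuclear-size
#' quarter `window_star`; otherwise the division is proliferative. A
#' `censor_frac` fraction of cells is cell-cycle arrested (at a phase past
#' the decision window, so the planted rule never fires for them) and never
#' divides. Intensities get multiplicative lognormal noise (sigma per
#' channel); nuclear size gets additive Gaussian noise at 2% of its range.
#'
#' @param n_roots,cells_per_root Dataset size (default 5 x 40).
#' @param dt Sampling interval, h (default 0.25).
#' @param horizon Observation horizon, h (default 48).
#' @param dex_dose Dose in uM (default 10, full induction). A vector is
#'   recycled over roots, emulating a dose-ladder experiment in which each
#'   root receives one concentration.
#' @param dose_half,dose_hill Dose-response map parameters: amplitude =
#'   `dose^h / (dose_half^h + dose^h)` (default half-point 0.15 uM, h 1.5).
#' @param onset_delay,rise_rate Sigmoid SHR shape (h, h^-1).
#' @param amp_cv Lognormal sigma of per-cell amplitude scatter around the
#'   root's dose-set amplitude (default 0.25), reflecting the wide
#'   cell-to-cell variation of reporter accumulation within a root.
#' @param pulse_width,pulse_decay Optional transient-pulse mode: when
#'   `pulse_width` is finite, SHR decays at rate `pulse_decay` (h^-1) after
#'   `onset_delay + pulse_width`, emulating low transient induction peaks.
#' @param scr_model [ode_model_spec()] driving SCR from SHR.
#' @param cycle_median,cycle_sdlog Lognormal cell-cycle length (median 12 h).
#' @param size_min,size_max Nuclear size range, arbitrary units.
#' @param g1_fraction Mean fraction of the cycle occupied by G1 (default
#'   0.35).
#' @param g1_fraction_sd Cycle-to-cycle standard deviation of the G1
#'   fraction (truncated normal, default 0.15); G1 duration is the most
#'   variable cell-cycle phase.
#' @param theta_star,channel_star,window_star Planted decision rule:
#'   threshold (normalized units), channel, nuclear-size quarter.
#' @param noise_sigma Multiplicative lognormal sigma for intensities.
#' @param size_noise_frac Additive size noise as a fraction of the range.
#' @param censor_frac Fraction of never-dividing (arrested) cells.
#' @param seed Master seed; per-cell streams are derived by a stable hash of
#'   (seed, root, cell, dose) so subsets regenerate identically.
#' @return A validated `synthetic_config`.
#' @export
synthetic_config <- function(n_roots = 5L, cells_per_root = 40L,
                             dt = 0.25, horizon = 48,
                             dex_dose = 10,
                             dose_half = 0.15, dose_hill = 1.5,
                             onset_delay = 3, rise_rate = 0.4,
                             amp_cv = 0.25,
                             pulse_width = Inf, pulse_decay = 0.2,
                             scr_model = ode_model_spec("michaelis_menten"),
                             cycle_median = 12, cycle_sdlog = 0.2,
                             size_min = 40, size_max = 110,
                             g1_fraction = 0.35, g1_fraction_sd = 0.15,
                             theta_star = 0.3, channel_star = "shr",
                             window_star = 1L,
                             noise_sigma = 0.1, size_noise_frac = 0.02,
                             censor_frac = 0.1, seed = 1L) {
  cfg <- as.list(environment())
  assert_that(n_roots >= 1 && cells_per_root >= 1, "dataset must be non-empty",
              "shrscr_config_error")
  assert_that(dt > 0 && horizon > dt, "invalid sampling grid",
              "shrscr_config_error")
  assert_that(all(dex_dose >= 0) && dose_half > 0 && dose_hill > 0,
              "invalid dose map", "shrscr_config_error")
  assert_that(theta_star > 0 && window_star %in% 1:4 &&
                channel_star %in% c("shr", "scr"),
              "invalid decision rule", "shrscr_config_error")
  assert_that(censor_frac >= 0 && censor_frac < 1, "invalid censor_frac",
              "shrscr_config_error")
  assert_that(noise_sigma >= 0 && size_noise_frac >= 0 && amp_cv >= 0 &&
                g1_fraction >= 0 && g1_fraction <= 1,
              "invalid noise/G1 settings", "shrscr_config_error")
  assert_that(size_max > size_min && size_min > 0, "invalid size range",
              "shrscr_config_error")
  assert_that(inherits(scr_model, "ode_model_spec"), "scr_model must be an ode_model_spec",
              "shrscr_config_error")
  structure(cfg, class = "synthetic_config")
}

#' Dose to SHR plateau amplitude map (monotone non-decreasing)
#' @param config A `synthetic_config`. @param dose Dose(s) in uM.
#' @return Amplitude in normalized units.
#' @export
dose_amplitude <- function(config, dose = config$dex_dose) {
  dose^config$dose_hill / (config$dose_half^config$dose_hill +
                             dose^config$dose_hill)
}

#' Noiseless SHR input curve for a dose
#' @noRd
shr_curve <- function(config, times, amplitude) {
  p0 <- stats::plogis(-config$rise_rate * config$onset_delay)
  s <- amplitude * (stats::plogis(config$rise_rate * (times - config$onset_delay)) -
                      p0) / (1 - p0)
  s <- pmax(s, 0)
  if (is.finite(config$pulse_width)) {
    t_off <- config$onset_delay + config$pulse_width
    s <- s * exp(-pmax(times - t_off, 0) * config$pulse_decay)
  }
  s
}

#' Generate a synthetic trajectory dataset with ground truth
#'
#' See [synthetic_config()] for the generative model. The returned ground
#' truth stores the planted rule, each cell's label, and its noiseless
#' series with the true cycle phase, so planted labels can be re-derived by
#' re-applying the decision rule (self-consistency).
#'
#' @param config A [synthetic_config()].
#' @return List with `trajectories` (a `trajectory_set`) and `ground_truth`
#'   (list: `theta_star`, `window_star`, `channel_star`, `cells` — per-cell
#'   label and noiseless series).
#' @export
generate_trajectories <- function(config) {
  assert_that(inherits(config, "synthetic_config"), "invalid config",
              "shrscr_config_error")
  times_full <- seq(0, config$horizon, by = config$dt)
  root_dose <- rep_len(config$dex_dose, config$n_roots)
  size_range <- config$size_max - config$size_min
  w_lo <- (config$window_star - 1) / 4
  w_hi <- config$window_star / 4
  in_window <- function(phase) {
    if (config$window_star == 4L) phase >= w_lo & phase <= w_hi
    else phase >= w_lo & phase < w_hi
  }

  trajs <- list(); truth_cells <- list()
  for (r in seq_len(config$n_roots)) {
    root_id <- sprintf("root%02d", r)
    dose_r <- root_dose[r]
    amplitude_root <- dose_amplitude(config, dose_r)
    for (c in seq_len(config$cells_per_root)) {
      cell_id <- sprintf("cell%03d", c)
      set.seed(child_seed(config$seed, root_id, cell_id, dose_r))
      arrested <- stats::runif(1) < config$censor_frac
      phase0 <- stats::runif(1)
      # per-cell reporter amplitude scatters around the root's dose level
      amplitude <- amplitude_root * stats::rlnorm(1, 0, config$amp_cv)
      shr_true_full <- shr_curve(config, times_full, amplitude)
      scr_true_full <- predict_scr_fast(config$scr_model, times_full,
                                        shr_true_full)

      if (arrested) {
        # arrested past the decision window: never divides, rule never fires
        arrest_phase <- stats::runif(1, min = min(w_hi + 0.05, 0.95), max = 1)
        n_t <- length(times_full)
        phase <- rep(arrest_phase, n_t)
        cycle_idx <- rep(1L, n_t)
        divisions <- empty_divisions()
        label <- "censored"
        keep <- rep(TRUE, n_t)
      } else {
        # lay out cycles; the first began before induction (uniform phase)
        cycle_len <- function() stats::rlnorm(1, meanlog = log(config$cycle_median),
                                              sdlog = config$cycle_sdlog)
        L1 <- cycle_len()
        starts <- -phase0 * L1
        lens <- L1
        while (starts[length(starts)] + lens[length(lens)] < config$horizon &&
               length(lens) < 50L) {
          starts <- c(starts, starts[length(starts)] + lens[length(lens)])
          lens <- c(lens, cycle_len())
        }
        ends <- starts + lens
        # half-open cycle membership [start, end): each sample sits in one cycle
        cycle_idx_full <- rep(NA_integer_, length(times_full))
        phase_full <- rep(NA_real_, length(times_full))
        for (i in seq_along(lens)) {
          sel <- times_full >= starts[i] & times_full < ends[i]
          cycle_idx_full[sel] <- i
          phase_full[sel] <- (times_full[sel] - starts[i]) / lens[i]
        }
        left <- is.na(cycle_idx_full)   # horizon beyond the last laid-out cycle
        if (any(left)) {
          i <- length(lens)
          cycle_idx_full[left] <- i
          phase_full[left] <- pmin((times_full[left] - starts[i]) / lens[i], 1)
        }
        v_true_full <- if (config$channel_star == "shr") shr_true_full else scr_true_full
        label <- "censored"
        divisions <- empty_divisions()
        t_stop <- config$horizon
        for (i in seq_along(lens)) {
          if (ends[i] > config$horizon) break   # cycle not completed in view
          hit <- any(cycle_idx_full == i & in_window(phase_full) &
                       v_true_full >= config$theta_star)
          # the division is recorded on the last sampled frame of its cycle,
          # so the post-division size reset falls into the next segment
          div_frame <- max(times_full[times_full < ends[i]])
          divisions <- rbind(divisions, data.frame(
            time = div_frame,
            orientation = if (hit) "formative" else "proliferative",
            stringsAsFactors = FALSE))
          if (hit) { label <- "formative"; t_stop <- div_frame; break }
          label <- "proliferative"
        }
        keep <- times_full <= t_stop
        phase <- phase_full[keep]
        cycle_idx <- cycle_idx_full[keep]
      }

      tk <- times_full[keep]
      shr_true <- shr_true_full[keep]
      scr_true <- scr_true_full[keep]
      size_true <- config$size_min + size_range * phase
      n_t <- length(tk)
      shr_obs <- shr_true * exp(stats::rnorm(n_t, 0, config$noise_sigma))
      scr_obs <- scr_true * exp(stats::rnorm(n_t, 0, config$noise_sigma))
      size_obs <- pmax(size_true +
                         stats::rnorm(n_t, 0, config$size_noise_frac * size_range),
                       0.01 * config$size_min)
      tr <- cell_trajectory(cell_id, root_id, tk, shr_obs, scr = scr_obs,
                            nuclear_size = size_obs, divisions = divisions,
                            censored = label != "formative",
                            dataset = "lightsheet", dex_dose = dose_r)
      trajs[[paste(root_id, cell_id, sep = "/")]] <- tr
      truth_cells[[paste(root_id, cell_id, sep = "/")]] <- list(
        root_id = root_id, cell_id = cell_id, label = label,
        dex_dose = dose_r, amplitude = amplitude,
        times = tk, shr_true = shr_true, scr_true = scr_true,
        phase = phase, cycle_index = cycle_idx, size_true = size_true,
        n_divisions = nrow(divisions), arrested = arrested)
    }
  }
  class(trajs) <- "trajectory_set"
  list(trajectories = trajs,
       ground_truth = list(theta_star = config$theta_star,
                           window_star = config$window_star,
                           channel_star = config$channel_star,
                           root_dose = root_dose,
                           cells = truth_cells))
}

#' Re-apply the planted decision rule to stored noiseless ground truth
#'
#' Self-consistency oracle: recomputes each cell's label from its noiseless
#' channel, true cycle phase and the planted rule; must equal the stored
#' labels for every generated dataset.
#'
#' @param result Output of [generate_trajectories()].
#' @param config The [synthetic_config()] used.
#' @return Named character vector of re-derived labels.
#' @export
replay_decision_rule <- function(result, config) {
  gt <- result$ground_truth
  w <- gt$window_star
  in_w <- function(phase) {
    lo <- (w - 1) / 4; hi <- w / 4
    if (w == 4L) phase >= lo & phase <= hi else phase >= lo & phase < hi
  }
  vapply(gt$cells, function(cell) {
    if (cell$arrested) return("censored")
    v <- if (gt$channel_star == "shr") cell$shr_true else cell$scr_true
    hit_point <- in_w(cell$phase) & v >= gt$theta_star
    # the rule fires per completed cycle; completed cycles are 1..n_divisions
    completed <- seq_len(cell$n_divisions)
    fired <- vapply(completed, function(i)
      any(hit_point & cell$cycle_index == i), TRUE)
    if (length(fired) && any(fired)) "formative"
    else if (cell$n_divisions > 0L) "proliferative"
    else "censored"
  }, "")
}

#' Generate datasets across a dex dose series
#'
#' All non-dose parameters are shared; per-cell seeds are derived from
#' (seed, root, cell, dose), so the result for one dose is independent of
#' the order in which doses are requested.
#'
#' @param config Base [synthetic_config()].
#' @param doses Numeric vector of doses, uM.
#' @return Named list (one element per dose) of
#'   [generate_trajectories()] results.
#' @export
generate_dose_series <- function(config, doses) {
  assert_that(all(doses >= 0), "doses must be non-negative", "shrscr_config_error")
  out <- lapply(doses, function(d) {
    cfg <- config
    cfg$dex_dose <- d
    generate_trajectories(cfg)
  })
  names(out) <- vapply(doses, function(d) format(d, trim = TRUE), "")
  out
}

#' Fraction of formative cells in a generated dataset
#'
#' By default the rescue-style fraction among dividing cells (formative
#' divisions over all cells that divided); `among = "all"` divides by every
#' generated cell instead.
#'
#' @param result Output of [generate_trajectories()].
#' @param among `"dividing"` (default) or `"all"`.
#' @return Scalar fraction (`NaN` when no cell divided and
#'   `among = "dividing"`).
#' @export
formative_fraction <- function(result, among = c("dividing", "all")) {
  among <- match.arg(among)
  labels <- vapply(result$ground_truth$cells, `[[`, "", "label")
  if (among == "dividing") {
    divided <- labels %in% c("formative", "proliferative")
    if (!any(divided)) return(NaN)
    mean(labels[divided] == "formative")
  } else {
    mean(labels == "formative")
  }
}

#' Emit complete cycles with a G1 marker for concordance analysis
#'
#' Generates `n_cycles` complete cell cycles: nuclear size grows linearly
#' (with the configured additive noise) across the cycle, and the G1 marker
#' is on for the first `g1_fraction` of the cycle duration. Suitable as
#' input for [g1_window_concordance()]; the ground-truth concordance is
#' computable by direct enumeration on the noiseless series.
#'
#' @param config A [synthetic_config()].
#' @param n_cycles Number of cycles, default 40.
#' @param n_roots Number of roots the cycles are attributed to, default 2.
#' @return List of cycles: `times`, `g1_on`, `size`, `root_id`.
#' @export
emit_cycle_marker_set <- function(config, n_cycles = 40L, n_roots = 2L) {
  size_range <- config$size_max - config$size_min
  lapply(seq_len(n_cycles), function(i) {
    set.seed(child_seed(config$seed, "g1cycle", i))
    L <- stats::rlnorm(1, log(config$cycle_median), config$cycle_sdlog)
    g1f <- min(max(stats::rnorm(1, config$g1_fraction, config$g1_fraction_sd),
                   0.02), 0.9)
    tt <- seq(0, L, by = config$dt)
    size <- config$size_min + size_range * (tt / L) +
      stats::rnorm(length(tt), 0, config$size_noise_frac * size_range)
    list(times = tt, g1_on = tt <= g1f * L,
         size = pmax(size, 1e-6),
         root_id = sprintf("root%02d", 1L + (i - 1L) %% n_roots))
  })
}

#' Write the planted ground truth as a JSON side-car
#'
#' Records the decision rule (threshold, window, channel), the per-root
#' doses, and each cell's planted label and dose -- enough to audit any
#' downstream classification without carrying the full noiseless series.
#'
#' @param result Output of [generate_trajectories()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth_json <- function(result, path) {
  gt <- result$ground_truth
  cells <- lapply(gt$cells, function(c)
    list(root_id = c$root_id, cell_id = c$cell_id, label = c$label,
         dex_dose = c$dex_dose, arrested = c$arrested,
         n_divisions = c$n_divisions))
  jsonlite::write_json(
    list(theta_star = gt$theta_star, window_star = gt$window_star,
         channel_star = gt$channel_star, root_dose = gt$root_dose,
         cells = unname(cells)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Recover the planted decision window and threshold from synthetic data
#'
#' Pipeline-closure experiment: generates a dataset, smooths the decision
#' channel, segments cycles, runs the windowed threshold scan in all four
#' nuclear-size quarters, and ranks single features. Because the generator
#' emits intensities already on the normalized scale, no quantile
#' renormalization is applied, so the recovered threshold is directly
#' comparable to the planted one.
#'
#' @param config A [synthetic_config()].
#' @param grid Threshold grid for the scan; default steps of 0.05 over
#'   `[0, 1]`, a resolution commensurate with the measurement noise.
#' @param smooth_window Smoothing window (frames), default 5.
#' @return List: `quarter_accuracy` (length 4), `best_quarter`,
#'   `best_theta` (of the winning quarter), `scans`, `top_feature`,
#'   `feature_ranking`.
#' @export
recover_decision_window <- function(config, grid = seq(0, 1, by = 0.05),
                                    smooth_window = 5L) {
  res <- generate_trajectories(config)
  ch <- config$channel_star
  trajs <- lapply(res$trajectories, function(tr) {
    tr[[ch]] <- smooth_series(tr[[ch]], smooth_window)
    tr
  })
  segs <- collect_segments(trajs)
  scans <- windowed_scan_all_quarters(segs, ch, grid = grid)
  acc <- vapply(scans, `[[`, 0, "best_accuracy")
  best_q <- which.max(acc)
  tab <- feature_table(segs, channels = ch)
  ranking <- single_feature_discrimination(tab)
  list(quarter_accuracy = acc, best_quarter = unname(best_q),
       best_theta = scans[[best_q]]$best_theta, scans = scans,
       top_feature = ranking$feature[1L], feature_ranking = ranking)
}

#' Synthesize a first-division table under cell-cycle synchronization
#'
#' Emulates the synchronization comparison. Control cells sit at a uniformly
#' random cycle phase at induction and cycle freely. Synchronized cells are
#' arrested by the drug at the synchronization point -- late G1 / G1-S
#' boundary (phase 0.05-0.25) for hydroxyurea, G2/M (phase 0.80-0.98) for
#' oryzalin -- and hold that phase for `release_delay` hours after induction
#' while SHR accumulates, then resume cycling. Each cell's first division
#' after induction is recorded with the orientation given by the planted
#' rule evaluated over its (arrest-aware) phase trajectory.
#'
#' @param config A [synthetic_config()].
#' @param treatments Character vector of treatments to synthesize.
#' @param roots_per_treatment Roots per treatment, default 3.
#' @param cells_per_root Cells per root, default 30.
#' @param release_delay Hours a synchronized cell remains arrested after
#'   induction, default 4.
#' @return Data frame (root_id, treatment, cell_id, orientation) suitable
#'   for [first_division_summary()].
#' @export
synthesize_division_table <- function(config,
                                      treatments = c("control", "hydroxyurea",
                                                     "oryzalin"),
                                      roots_per_treatment = 3L,
                                      cells_per_root = 30L,
                                      release_delay = 4) {
  times_full <- seq(0, config$horizon, by = config$dt)
  amplitude <- dose_amplitude(config, config$dex_dose[1L])
  shr_true <- shr_curve(config, times_full, amplitude)
  scr_true <- predict_scr_fast(config$scr_model, times_full, shr_true)
  v_true <- if (config$channel_star == "shr") shr_true else scr_true
  w_lo <- (config$window_star - 1) / 4; w_hi <- config$window_star / 4
  rows <- list()
  for (tr in treatments) {
    for (r in seq_len(roots_per_treatment)) {
      root_id <- sprintf("%s_root%02d", tr, r)
      for (c in seq_len(cells_per_root)) {
        set.seed(child_seed(config$seed, "sync", tr, r, c))
        phase0 <- switch(tr,
                         hydroxyurea = stats::runif(1, 0.05, 0.25),
                         oryzalin = stats::runif(1, 0.80, 0.98),
                         stats::runif(1))
        hold <- if (tr == "control") 0 else release_delay
        L <- stats::rlnorm(1, log(config$cycle_median), config$cycle_sdlog)
        # phase holds at phase0 during arrest, then advances linearly
        ph <- ifelse(times_full <= hold, phase0,
                     phase0 + (times_full - hold) / L)
        in_view <- ph <= 1
        hit <- ph[in_view] >= w_lo & ph[in_view] < w_hi &
          v_true[in_view] >= config$theta_star
        rows[[length(rows) + 1L]] <- data.frame(
          root_id = root_id, treatment = tr,
          cell_id = sprintf("cell%03d", c),
          orientation = if (any(hit)) "formative" else "proliferative",
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
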