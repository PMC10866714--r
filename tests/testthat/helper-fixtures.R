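# Shared fixtures, built in code.

# A minimal two-cell long-format table written to a temp CSV.
write_toy_csv <- function(path = tempfile(fileext = ".csv"),
                          duplicate_row = FALSE, negative = FALSE) {
  tab <- data.frame(
    root_id = "r1",
    cell_id = rep(c("a", "b"), each = 4),
    time_h = rep(c(0, 0.25, 0.5, 0.75), 2),
    shr = c(0.1, 0.2, 0.3, 0.4, 1, 2, 3, 4),
    scr = c(0.05, 0.1, 0.15, 0.2, 0.5, 1, 1.5, 2),
    nuclear_size = c(40, 50, 60, 70, 45, 55, 65, 75),
    event = "",
    orientation = "",
    stringsAsFactors = FALSE)
  if (duplicate_row) tab <- rbind(tab, tab[2, ])
  if (negative) tab$shr[3] <- -1
  utils::write.csv(tab, path, row.names = FALSE)
  path
}

# Hand-built trajectory with one proliferative and one formative division.
toy_trajectory <- function() {
  tt <- seq(0, 12, by = 0.5)
  cell_trajectory(
    cell_id = "c1", root_id = "r1", times = tt,
    shr = seq(0.1, 1, length.out = length(tt)),
    nuclear_size = c(seq(50, 100, length.out = 11),
                     seq(45, 105, length.out = 14)),
    divisions = data.frame(time = c(5, 12),
                           orientation = c("proliferative", "formative")))
}

# Synthetic classification units: "segments" with known channel values and
# outcomes, enough structure for threshold scans.
toy_units <- function(values_formative, values_other,
                      other_label = "censored") {
  mk <- function(v, outcome, id) {
    structure(list(cell_id = id, root_id = "r", index = 1L,
                   times = seq_along(v) * 0.25, shr = v,
                   norm_size = seq(0, 1, length.out = length(v)),
                   outcome = outcome),
              class = "cell_cycle_segment")
  }
  c(lapply(seq_along(values_formative), function(i)
      mk(values_formative[[i]], "formative", paste0("f", i))),
    lapply(seq_along(values_other), function(i)
      mk(values_other[[i]], other_label, paste0("o", i))))
}

# Dose ladder emulating the inducible confocal experiment.
dose_ladder <- c(0.01, 0.02, 0.03, 0.05, 0.1, 0.2, 1, 10)

ladder_config <- function(seed = 1L, n_roots = 8L, cells_per_root = 25L, ...) {
  synthetic_config(n_roots = n_roots, cells_per_root = cells_per_root,
                   dex_dose = dose_ladder, seed = seed, ...)
}

# Brute-force fixed-step RK4 integrator, independent of simulate_model().
rk4_oracle <- function(spec, h_fun, grid, init = 0, dt = 1e-3) {
  f <- function(t, y) shrscr:::model_rhs(spec, y, h_fun(t))
  out <- numeric(length(grid))
  y <- init
  out[1] <- if (length(init) == 1L) init else init[1]
  for (i in seq_len(length(grid) - 1L)) {
    t <- grid[i]
    n_steps <- max(1L, ceiling((grid[i + 1] - t) / dt))
    h <- (grid[i + 1] - t) / n_steps
    for (k in seq_len(n_steps)) {
      k1 <- f(t, y)
      k2 <- f(t + h / 2, y + h / 2 * k1)
      k3 <- f(t + h / 2, y + h / 2 * k2)
      k4 <- f(t + h, y + h * k3)
      y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      t <- t + h
    }
    out[i + 1] <- y[1]
  }
  out
}

# Dense 1-D sign-change scan for fixed points of one-state families.
grid_scan_oracle <- function(spec, h, s_max = 10, step = 1e-4) {
  s <- seq(0, s_max, by = step)
  f <- vapply(s, function(x) shrscr:::model_rhs(spec, x, h), numeric(1))
  sign_change <- which(f[-1] * f[-length(f)] <= 0 & f[-1] != f[-length(f)])
  roots <- vapply(sign_change, function(i) {
    uniroot(function(x) shrscr:::model_rhs(spec, x, h),
            c(s[i], s[i + 1]), tol = 1e-12)$root
  }, numeric(1))
  unique(round(roots, 8))
}
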