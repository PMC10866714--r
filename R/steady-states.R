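# Fixed-point location, stability classification, and bistability scans.

numerical_jacobian <- function(f, x, eps = 1e-7) {
  n <- length(x)
  f0 <- f(x)
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    h <- eps * max(abs(x[j]), 1)
    xp <- x; xp[j] <- xp[j] + h
    J[, j] <- (f(xp) - f0) / h
  }
  J
}

#' Locate fixed points of a model at a constant SHR input
#'
#' Damped Newton iteration with a numerical Jacobian, started from a lattice
#' of initial states (`starts_per_dim` points log-spaced over
#' `[1e-3, 1e2]` per state dimension). For one-dimensional families the
#' lattice is supplemented by a sign-change pre-scan over `[0, 102]` with
#' `uniroot` refinement, which reliably separates closely spaced fixed
#' points near a fold bifurcation. Converged roots are merged within
#' `merge_tol`; stability is classified by the sign of the real parts of
#' the Jacobian eigenvalues at the root.
#'
#' @param spec An [ode_model_spec()].
#' @param shr_level Constant input level (non-negative).
#' @param starts_per_dim Lattice resolution per state dimension, default 5.
#' @param merge_tol Roots closer than this (absolutely) are merged.
#' @param ftol Residual norm below which a Newton run counts as converged.
#' @return Data frame with one row per fixed point: the state columns plus
#'   `stable` (logical). Zero rows when no root is found (logged as
#'   suspicious via a warning).
#' @export
find_steady_states <- function(spec, shr_level, starts_per_dim = 5L,
                               merge_tol = 1e-6, ftol = 1e-10) {
  assert_that(shr_level >= 0, "'shr_level' must be non-negative")
  sn <- state_names(spec)
  d <- length(sn)
  f <- function(x) model_rhs(spec, x, shr_level)
  axis <- 10^seq(-3, 2, length.out = starts_per_dim)
  lattice <- as.matrix(do.call(expand.grid, rep(list(axis), d)))

  roots <- list()
  for (i in seq_len(nrow(lattice))) {
    x <- as.numeric(lattice[i, ])
    ok <- FALSE
    for (iter in 1:50) {
      fx <- f(x)
      if (sqrt(sum(fx^2)) < ftol) { ok <- TRUE; break }
      J <- numerical_jacobian(f, x)
      step <- tryCatch(solve(J, -fx), error = function(e) NULL)
      if (is.null(step)) break
      # damped update, states kept non-negative
      lambda <- 1
      repeat {
        xn <- pmax(x + lambda * step, 0)
        if (sqrt(sum(f(xn)^2)) < sqrt(sum(fx^2)) || lambda < 1e-6) break
        lambda <- lambda / 2
      }
      if (sqrt(sum((xn - x)^2)) < 1e-14) { x <- xn; fx2 <- f(x); ok <- sqrt(sum(fx2^2)) < ftol * 1e4; break }
      x <- xn
    }
    if (ok && all(is.finite(x)) && all(x >= -merge_tol)) {
      roots[[length(roots) + 1L]] <- pmax(x, 0)
    }
  }
  if (d == 1L) {
    s_grid <- seq(0, 102, length.out = 2048L)
    fv <- vapply(s_grid, f, numeric(1))
    change <- which(fv[-1L] * fv[-length(fv)] <= 0 & fv[-1L] != fv[-length(fv)])
    for (i in change) {
      r <- tryCatch(
        stats::uniroot(function(s) f(s), c(s_grid[i], s_grid[i + 1L]),
                       tol = 1e-12)$root,
        error = function(e) NULL)
      if (!is.null(r)) roots[[length(roots) + 1L]] <- r
    }
  }
  if (length(roots) == 0L) {
    warning(sprintf("no fixed point found for family '%s' at input %.3g",
                    spec$family, shr_level))
    out <- as.data.frame(matrix(numeric(0), 0, d))
    names(out) <- sn
    out$stable <- logical(0)
    return(out)
  }
  merged <- list(roots[[1L]])
  for (r in roots[-1L]) {
    if (all(vapply(merged, function(m)
      sqrt(sum((m - r)^2)) > merge_tol * (1 + sqrt(sum(r^2))), TRUE))) {
      merged[[length(merged) + 1L]] <- r
    }
  }
  stable <- vapply(merged, function(r) {
    ev <- eigen(numerical_jacobian(f, r), only.values = TRUE)$values
    all(Re(ev) < 0)
  }, TRUE)
  states <- do.call(rbind, merged)
  out <- as.data.frame(states)
  names(out) <- sn
  out$stable <- stable
  out[order(out[[1L]]), , drop = FALSE]
}

#' Scan an input range for bistability
#'
#' Runs [find_steady_states()] across a grid of constant SHR inputs and
#' reports the number of stable fixed points at each level. The system is
#' called bistable when two or more stable states coexist at some input; the
#' hysteresis interval is the input range over which they do.
#'
#' @param spec An [ode_model_spec()].
#' @param input_range Length-2 non-negative interval of SHR inputs.
#' @param n_grid Number of grid points, at least 2.
#' @param ... Passed to [find_steady_states()].
#' @return A `bistability_report`: list with `input_grid`, `stable_counts`,
#'   `bistable` flag and `hysteresis_interval` (length 0 when monostable).
#' @export
bistability_check <- function(spec, input_range, n_grid = 25L, ...) {
  assert_that(length(input_range) == 2L && all(input_range >= 0) &&
                input_range[2L] >= input_range[1L],
              "'input_range' must be a non-negative increasing interval")
  assert_that(n_grid >= 2L, "'n_grid' must be at least 2")
  grid <- seq(input_range[1L], input_range[2L], length.out = n_grid)
  counts <- vapply(grid, function(h) {
    ss <- suppressWarnings(find_steady_states(spec, h, ...))
    sum(ss$stable)
  }, integer(1))
  multi <- counts >= 2L
  interval <- if (any(multi)) range(grid[multi]) else numeric(0)
  structure(list(input_grid = grid, stable_counts = counts,
                 bistable = any(multi), hysteresis_interval = interval),
            class = "bistability_report")
}

#' @export
print.bistability_report <- function(x, ...) {
  cat(sprintf("<bistability_report: %s; max stable states %d%s>\n",
              if (x$bistable) "BISTABLE" else "monostable",
              max(x$stable_counts),
              if (x$bistable) sprintf(", hysteresis over [%.3g, %.3g]",
                                      x$hysteresis_interval[1L],
                                      x$hysteresis_interval[2L]) else ""))
  invisible(x)
}

#' One-at-a-time parameter scan of fit quality and bistability
#'
#' Varies each model parameter over a multiplicative factor grid (spanning
#' two orders of magnitude by default, always including 1) while holding the
#' others at their values in `spec`. For every (parameter, factor) cell the
#' model's SCR prediction driven by `shr_mean` is re-evaluated against
#' `scr_mean` (adjusted R-squared) and the input range is re-checked for
#' bistability. Integration failures are recorded per cell and the scan
#' continues.
#'
#' @param spec Baseline [ode_model_spec()].
#' @param shr_mean,scr_mean Mean trajectories on one grid.
#' @param factors Multiplicative factors; must include 1.
#' @param input_range Input interval for [bistability_check()].
#' @param n_grid Bistability grid resolution.
#' @param init Initial state for the prediction (default zero).
#' @param ... Passed to [find_steady_states()] via [bistability_check()]
#'   (e.g. `starts_per_dim` to coarsen the root-search lattice).
#' @return Tidy data frame: `parameter`, `factor`, `value`, `r2_adj`,
#'   `bistable`, `error`.
#' @export
parameter_scan <- function(spec, shr_mean, scr_mean,
                           factors = 10^seq(-2, 2, by = 0.5),
                           input_range = c(0, 1.5), n_grid = 15L,
                           init = NULL, ...) {
  assert_that(any(abs(factors - 1) < 1e-12), "'factors' must include 1")
  t_grid <- shr_mean$time %||% shr_mean$times
  observed <- scr_mean$mean
  h_fun <- as_input_fun(list(times = t_grid, values = shr_mean$mean))
  p_free <- length(spec$params)
  rows <- list()
  for (pname in names(spec$params)) {
    for (f in factors) {
      pars <- spec$params
      pars[pname] <- pars[pname] * f
      row <- data.frame(parameter = pname, factor = f,
                        value = unname(pars[pname]),
                        r2_adj = NA_real_, bistable = NA, error = "",
                        stringsAsFactors = FALSE)
      res <- tryCatch({
        sp <- ode_model_spec(spec$family, pars)
        sim <- suppressWarnings(simulate_model(sp, h_fun, t_grid, init = init))
        pred <- predicted_scr(sim)
        bi <- bistability_check(sp, input_range, n_grid = n_grid, ...)
        list(r2 = adjusted_r2(observed, pred, p_free), bi = bi$bistable)
      }, error = function(e) conditionMessage(e))
      if (is.list(res)) {
        row$r2_adj <- res$r2; row$bistable <- res$bi
      } else {
        row$error <- res
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}
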