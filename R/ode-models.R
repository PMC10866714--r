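#' Candidate models of SCR regulation by SHR
#'
#' Constructs a model specification for one of the candidate families used to
#' describe SCR accumulation driven by an SHR input signal \eqn{H(t)}:
#'
#' * `michaelis_menten`: \eqn{dS/dt = \beta H/(K+H) - \gamma S}
#' * `hill`: \eqn{dS/dt = \beta H^{n}/(K^{n}+H^{n}) - \gamma S}
#' * `positive_feedback`: \eqn{dS/dt = \beta H/(K+H) + \alpha S/(K_f+S) - \gamma S}
#'   (saturating SCR autoregulation; monostable, since a concave production
#'   term crosses linear decay at most twice)
#' * `self_activation`: \eqn{dS/dt = H + \alpha S^2/(K_f^2+S^2) - \gamma S}, a
#'   minimal one-dimensional switch in which the input acts as basal
#'   production; used to exercise the bistability detector.
#' * `cruz_ramirez`: a reduced three-species transcription of the bistable
#'   SHR--SCR network of Cruz-Ramirez et al. (Cell, 2012): SCR production is
#'   activated by the SHR-SCR complex, free RBR sequesters SCR, and CYCD6
#'   (itself SHR-SCR activated) drives RBR phosphorylation, releasing SCR --
#'   two interlinked positive feedback loops. States are total SCR `C`,
#'   CYCD6 `D`, and phosphorylated RBR `Rp`; free SCR is
#'   \eqn{C_f = C/(1 + (R_{tot}-R_p)/K_R)} under rapid-equilibrium binding.
#'   The exact published parameter values are not reproduced here; the
#'   defaults are representative values chosen so the network is bistable
#'   over an intermediate range of SHR inputs.
#'
#' @param family Model family name.
#' @param params Named numeric vector/list overriding the family defaults.
#' @return An `ode_model_spec`.
#' @export
ode_model_spec <- function(family = c("michaelis_menten", "hill",
                                      "positive_feedback", "self_activation",
                                      "cruz_ramirez"),
                           params = list()) {
  family <- match.arg(family)
  defaults <- switch(family,
    michaelis_menten = c(beta = 0.25, K = 0.5, gamma = 0.15),
    hill = c(beta = 0.25, K = 0.5, n_h = 2, gamma = 0.15),
    positive_feedback = c(beta = 0.2, K = 0.5, alpha = 0.05, K_f = 0.5,
                          gamma = 0.15),
    self_activation = c(alpha = 1, K_f = 1, gamma = 0.45),
    cruz_ramirez = c(b0 = 0.01, beta_C = 1, K_C = 0.2, gamma_C = 0.1,
                     beta_D = 0.5, K_D = 0.2, gamma_D = 0.2,
                     k_p = 1, k_dp = 0.5, R_tot = 2, K_R = 0.2))
  params <- unlist(params)
  if (length(params)) {
    unknown <- setdiff(names(params), names(defaults))
    assert_that(length(unknown) == 0L,
                sprintf("unknown parameter(s) for family '%s': %s", family,
                        paste(unknown, collapse = ", ")))
    defaults[names(params)] <- params
  }
  assert_that(all(is.finite(defaults)), "model parameters must be finite")
  assert_that(all(defaults[setdiff(names(defaults), c("alpha", "b0"))] > 0),
              "rate and saturation constants must be positive")
  if ("n_h" %in% names(defaults)) {
    assert_that(defaults[["n_h"]] >= 1, "Hill coefficient must be >= 1")
  }
  structure(list(family = family, params = defaults), class = "ode_model_spec")
}

#' @export
print.ode_model_spec <- function(x, ...) {
  cat(sprintf("<ode_model_spec %s: %s>\n", x$family,
              paste(sprintf("%s=%.4g", names(x$params), x$params), collapse = ", ")))
  invisible(x)
}

state_names <- function(spec) {
  if (spec$family == "cruz_ramirez") c("C", "D", "Rp") else "S"
}

#' Right-hand side of a model at one state and input level
#' @noRd
model_rhs <- function(spec, state, h) {
  p <- spec$params
  switch(spec$family,
    michaelis_menten = unname(p["beta"] * h / (p["K"] + h) - p["gamma"] * state),
    hill = unname(p["beta"] * h^p["n_h"] / (p["K"]^p["n_h"] + h^p["n_h"]) -
                    p["gamma"] * state),
    positive_feedback = unname(p["beta"] * h / (p["K"] + h) +
                                 p["alpha"] * state / (p["K_f"] + state) -
                                 p["gamma"] * state),
    self_activation = unname(h + p["alpha"] * state^2 /
                               (p["K_f"]^2 + state^2) - p["gamma"] * state),
    cruz_ramirez = {
      C <- state[1L]; D <- state[2L]; Rp <- state[3L]
      R_free <- max(p[["R_tot"]] - Rp, 0)
      C_f <- C / (1 + R_free / p[["K_R"]])
      a <- h * C_f
      c(p[["b0"]] + p[["beta_C"]] * a^2 / (p[["K_C"]]^2 + a^2) - p[["gamma_C"]] * C,
        p[["beta_D"]] * a / (p[["K_D"]] + a) - p[["gamma_D"]] * D,
        p[["k_p"]] * D * R_free - p[["k_dp"]] * Rp)
    })
}

as_input_fun <- function(shr_input) {
  if (is.function(shr_input)) return(shr_input)
  if (inherits(shr_input, "mean_trajectory") || is.data.frame(shr_input)) {
    shr_input <- list(times = shr_input$time, values = shr_input$mean)
  }
  assert_that(is.list(shr_input) && all(c("times", "values") %in% names(shr_input)),
              "'shr_input' must be a function, mean_trajectory, or list(times, values)")
  # linear interpolation between samples, held constant beyond the ends
  stats::approxfun(shr_input$times, shr_input$values, rule = 2, ties = "ordered")
}

#' Integrate a model driven by an SHR input signal
#'
#' The input is linearly interpolated between its samples and held constant
#' beyond the last one. Integration uses `deSolve`: the stiff-capable `lsoda`
#' for the `cruz_ramirez` network and the adaptive explicit `ode45` pair for
#' the one-dimensional families. States that undershoot below `-clip_tol` are
#' clipped to zero with a warning.
#'
#' @param spec An [ode_model_spec()].
#' @param shr_input Function of time, `list(times, values)`, or a
#'   `mean_trajectory` (its `mean` column is used).
#' @param grid Increasing time grid, hours.
#' @param init Initial state, default zero.
#' @param rtol,atol Integrator tolerances.
#' @param clip_tol Undershoot beyond which a warning is raised.
#' @return Data frame with column `time` and one column per state; the
#'   predicted SCR series is the `S` (or `C`) column.
#' @export
simulate_model <- function(spec, shr_input, grid, init = NULL,
                           rtol = 1e-6, atol = 1e-9, clip_tol = 1e-6) {
  assert_that(!is.unsorted(grid, strictly = TRUE), "'grid' must be increasing")
  h_fun <- as_input_fun(shr_input)
  sn <- state_names(spec)
  if (is.null(init)) init <- stats::setNames(rep(0, length(sn)), sn)
  assert_that(length(init) == length(sn) && all(init >= 0),
              "'init' must be a non-negative state of the right dimension")
  deriv <- function(t, y, parms) list(model_rhs(spec, y, h_fun(t)))
  method <- if (spec$family == "cruz_ramirez") "lsoda" else "ode45"
  sol <- tryCatch(
    deSolve::ode(y = stats::setNames(as.numeric(init), sn), times = grid,
                 func = deriv, parms = NULL, method = method,
                 rtol = rtol, atol = atol),
    warning = function(w) {
      # deSolve signals step-size failures as warnings; surface as errors
      if (grepl("step size|too many", conditionMessage(w))) {
        abort_shrscr(sprintf("integration failed for family '%s' (%s): %s",
                             spec$family,
                             paste(sprintf("%s=%.3g", names(spec$params),
                                           spec$params), collapse = ", "),
                             conditionMessage(w)),
                     "shrscr_integration_error")
      }
      suppressWarnings(
        deSolve::ode(y = stats::setNames(as.numeric(init), sn), times = grid,
                     func = deriv, parms = NULL, method = method,
                     rtol = rtol, atol = atol))
    })
  out <- as.data.frame(sol)
  names(out)[1L] <- "time"
  states <- out[, -1L, drop = FALSE]
  if (any(states < -clip_tol, na.rm = TRUE)) {
    warning(sprintf("solver undershoot below -%g clipped to 0 (family %s)",
                    clip_tol, spec$family))
  }
  clipped <- pmax(as.matrix(states), 0)
  for (j in seq_len(ncol(clipped))) out[[j + 1L]] <- as.numeric(clipped[, j])
  if (anyNA(out)) {
    abort_shrscr(sprintf("integration failed for family '%s'", spec$family),
                 "shrscr_integration_error")
  }
  out
}

#' Predicted SCR series of a simulation result
#' @param sim Result of [simulate_model()].
#' @return Numeric vector.
#' @export
predicted_scr <- function(sim) {
  if ("S" %in% names(sim)) sim$S else sim$C
}

#' Adjusted coefficient of determination
#'
#' \eqn{R^2_{adj} = 1 - (1-R^2)(n-1)/(n-p-1)} with
#' \eqn{R^2 = 1 - SS_{res}/SS_{tot}}; `n_params` counts free (fitted)
#' parameters only.
#'
#' @param observed,predicted Equal-length numeric vectors.
#' @param n_params Number of free parameters `p`.
#' @return Scalar, at most 1.
#' @export
adjusted_r2 <- function(observed, predicted, n_params) {
  n <- length(observed)
  assert_that(length(predicted) == n, "'observed' and 'predicted' lengths differ")
  assert_that(n >= n_params + 2, "too few points for the parameter count")
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) {
    abort_shrscr("observed series has zero variance; R-squared undefined",
                 "shrscr_undefined_statistic_error")
  }
  ss_res <- sum((observed - predicted)^2)
  r2 <- 1 - ss_res / ss_tot
  1 - (1 - r2) * (n - 1) / (n - n_params - 1)
}

#' Fast SCR prediction for the one-dimensional driven families
#'
#' Used inside the fit objective, where the input curve is fixed across
#' thousands of objective evaluations. For Michaelis-Menten and Hill the ODE
#' is linear in S given the input, so each grid interval is advanced exactly
#' with the integrating factor and Simpson quadrature of the driven
#' production (input evaluated once at endpoints and midpoints). The
#' positive-feedback family is nonlinear in S and is advanced by fixed-step
#' RK4 with `substeps` steps per grid interval. The public
#' [simulate_model()] (adaptive, deSolve) remains the reference integrator;
#' the final fitted prediction is recomputed with it.
#' @noRd
fast_predict_1d <- function(family, params, h0, hm, grid, init = 0,
                            substeps = 2L) {
  p <- params
  drive <- function(h) {
    switch(family,
      michaelis_menten = p[["beta"]] * h / (p[["K"]] + h),
      hill = p[["beta"]] * h^p[["n_h"]] / (p[["K"]]^p[["n_h"]] + h^p[["n_h"]]),
      positive_feedback = p[["beta"]] * h / (p[["K"]] + h))
  }
  n <- length(grid)
  dt <- diff(grid)
  a0 <- drive(h0)             # input transformed at grid points
  am <- drive(hm)             # ... and at interval midpoints
  S <- numeric(n)
  S[1L] <- init
  if (family %in% c("michaelis_menten", "hill")) {
    g <- p[["gamma"]]
    E <- exp(-g * dt)
    b <- dt / 6 * (a0[-n] * E + 4 * am * sqrt(E) + a0[-1L])
    for (i in seq_len(n - 1L)) S[i + 1L] <- S[i] * E[i] + b[i]
  } else {
    al <- p[["alpha"]]; Kf <- p[["K_f"]]; g <- p[["gamma"]]
    # production interpolated linearly within each interval; RK4 node values
    # precomputed so the stepping loop is plain scalar arithmetic
    m <- substeps
    frac0 <- rep((seq_len(m) - 1) / m, n - 1L)
    idx <- rep(seq_len(n - 1L), each = m)
    da <- (a0[-1L] - a0[-n])[idx]
    aa <- a0[-n][idx] + da * frac0
    ab <- a0[-n][idx] + da * (frac0 + 1 / (2 * m))
    ac <- a0[-n][idx] + da * (frac0 + 1 / m)
    h_sub <- (dt / m)[idx]
    s <- init
    j <- 0L
    for (i in seq_len(n - 1L)) {
      for (k in seq_len(m)) {
        j <- j + 1L
        h2 <- h_sub[j] / 2
        k1 <- aa[j] + al * s / (Kf + s) - g * s
        s1 <- s + h2 * k1
        k2 <- ab[j] + al * s1 / (Kf + s1) - g * s1
        s2 <- s + h2 * k2
        k3 <- ab[j] + al * s2 / (Kf + s2) - g * s2
        s3 <- s + h_sub[j] * k3
        k4 <- ac[j] + al * s3 / (Kf + s3) - g * s3
        s <- s + h_sub[j] / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      }
      S[i + 1L] <- s <- max(s, 0)
    }
  }
  S
}

#' Predicted SCR series for a model driven by sampled SHR values
#'
#' Dispatches to the fast one-dimensional path for the driven monostable
#' families, and to [simulate_model()] otherwise.
#' @noRd
predict_scr_fast <- function(spec, times, shr_values, init = 0) {
  if (spec$family %in% c("michaelis_menten", "hill", "positive_feedback")) {
    n <- length(times)
    hm <- (shr_values[-1L] + shr_values[-n]) / 2
    fast_predict_1d(spec$family, as.list(spec$params), shr_values, hm, times,
                    init = init)
  } else {
    predicted_scr(simulate_model(spec, list(times = times, values = shr_values),
                                 times, init = init))
  }
}

free_params <- function(family) {
  switch(family,
    michaelis_menten = c("beta", "K", "gamma"),
    hill = c("beta", "K", "n_h", "gamma"),
    positive_feedback = c("beta", "K", "alpha", "K_f", "gamma"),
    self_activation = c("alpha", "K_f", "gamma"),
    cruz_ramirez = names(ode_model_spec("cruz_ramirez")$params))
}

#' Fit a model family to mean SHR and SCR trajectories
#'
#' Least-squares fit of the model's predicted SCR (driven by the mean SHR
#' series) to the mean SCR series, by bounded Levenberg-Marquardt
#' (`minpack.lm`) on log-scale parameters. A deterministic multi-start grid
#' (three log-spaced values per parameter around unit scale; Hill coefficients
#' start at 1, 2 and 4) guards against local minima; the best start wins, ties
#' broken by start order.
#'
#' @param family One of the monostable families (`"michaelis_menten"`,
#'   `"hill"`, `"positive_feedback"`).
#' @param shr_mean,scr_mean `mean_trajectory` objects (or data frames with
#'   `time` and `mean`) on the same grid.
#' @param starts_per_param Start-grid resolution, default 3.
#' @param n_refine Number of starts, ranked by their initial sum of squared
#'   residuals, that are refined by full Levenberg-Marquardt (default 20;
#'   the remaining starts are screened only). Deterministic: ties keep start
#'   order.
#' @param lower,upper Parameter bounds on the natural scale.
#' @param maxiter Levenberg-Marquardt iteration cap per start.
#' @return A `fit_result`: fitted spec, predicted series, `r2_adj`,
#'   residuals, `n_obs`, `n_params`, per-start diagnostics.
#' @export
fit_scr_model <- function(family = c("michaelis_menten", "hill",
                                     "positive_feedback"),
                          shr_mean, scr_mean, starts_per_param = 3L,
                          n_refine = 20L, lower = 1e-4, upper = 1e3,
                          maxiter = 300L) {
  family <- match.arg(family)
  t_shr <- shr_mean$time %||% shr_mean$times
  t_scr <- scr_mean$time %||% scr_mean$times
  assert_that(isTRUE(all.equal(t_shr, t_scr)),
              "SHR and SCR means must share one time grid")
  observed <- scr_mean$mean
  grid <- t_shr
  pn <- free_params(family)
  assert_that(length(observed) >= length(pn) + 2, "too few points to fit")
  h_fun <- as_input_fun(list(times = grid, values = shr_mean$mean))
  init_scr <- max(observed[1L], 0)
  n_g <- length(grid)
  h0 <- h_fun(grid)
  hm <- h_fun((grid[-n_g] + grid[-1L]) / 2)

  resid_fun <- function(logp) {
    p <- stats::setNames(exp(logp), pn)
    fast_predict_1d(family, as.list(p), h0, hm, grid, init = init_scr) - observed
  }

  k <- as.integer(starts_per_param)
  start_axis <- function(p) {
    if (p == "n_h") 2^seq(0, 2, length.out = k) else 10^seq(-1, 1, length.out = k)
  }
  axes <- lapply(pn, start_axis)
  starts <- as.matrix(do.call(expand.grid, axes))[, seq_along(pn), drop = FALSE]
  colnames(starts) <- pn

  lo <- stats::setNames(rep(log(lower), length(pn)), pn)
  hi <- stats::setNames(rep(log(upper), length(pn)), pn)
  if ("n_h" %in% pn) { lo["n_h"] <- log(1); hi["n_h"] <- log(10) }

  # screen all starts by initial SSR, refine only the most promising ones
  ssr0 <- vapply(seq_len(nrow(starts)), function(i)
    sum(resid_fun(log(starts[i, ]))^2), numeric(1))
  refine <- utils::head(order(ssr0), n_refine)

  best <- NULL
  diagnostics <- vector("list", length(refine))
  for (i in refine) {
    res <- tryCatch({
      f <- suppressWarnings(
        minpack.lm::nls.lm(par = log(starts[i, ]), lower = lo, upper = hi,
                           fn = resid_fun,
                           control = minpack.lm::nls.lm.control(
                             maxiter = maxiter, ptol = 1e-10, ftol = 1e-10)))
      list(par = f$par, ssr = sum(f$fvec^2), ok = TRUE, message = f$message)
    }, error = function(e) list(ok = FALSE, message = conditionMessage(e),
                                ssr = Inf))
    diagnostics[[match(i, refine)]] <- data.frame(start = i, ssr = res$ssr,
                                                  ok = res$ok,
                                                  message = res$message)
    if (res$ok && (is.null(best) || res$ssr < best$ssr - 1e-14)) best <- res
  }
  if (is.null(best)) {
    abort_shrscr(sprintf("all %d starts failed for family '%s'", nrow(starts),
                         family), "shrscr_fitting_error")
  }
  spec <- ode_model_spec(family, stats::setNames(exp(best$par), pn))
  pred <- predicted_scr(suppressWarnings(
    simulate_model(spec, h_fun, grid, init = c(S = init_scr))))
  structure(
    list(spec = spec, predicted = pred, observed = observed, time = grid,
         r2_adj = adjusted_r2(observed, pred, length(pn)),
         residuals = observed - pred,
         n_obs = length(observed), n_params = length(pn),
         start_diagnostics = do.call(rbind, diagnostics)),
    class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result %s: r2_adj = %.4f, n = %d, p = %d>\n",
              x$spec$family, x$r2_adj, x$n_obs, x$n_params))
  print(x$spec)
  invisible(x)
}

#' Export a fit result as a JSON report
#' @param fit A `fit_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  jsonlite::write_json(
    list(family = fit$spec$family, params = as.list(fit$spec$params),
         r2_adj = fit$r2_adj, n_obs = fit$n_obs, n_params = fit$n_params),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
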