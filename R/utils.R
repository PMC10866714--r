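# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Signal a classed error
#'
#' All user-facing validation failures in the package raise conditions with a
#' package-specific class so callers can distinguish schema errors from, say,
#' integration failures.
#' @noRd
abort_shrscr <- function(message, class) {
  stop(errorCondition(message, class = c(class, "shrscr_error")))
}

assert_that <- function(ok, message, class = "shrscr_argument_error") {
  if (!isTRUE(ok)) abort_shrscr(message, class)
  invisible(TRUE)
}

#' Trapezoidal integral of y over x
#' @noRd
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) / 2 * diff(x))
}

#' Stable 31-bit hash of a character key (FNV-1a folded below 2^31)
#'
#' Used to derive reproducible child seeds from (master seed, root, cell, dose)
#' so any subset of a synthetic dataset can be regenerated in isolation.
#' @noRd
stable_hash31 <- function(key) {
  bytes <- utf8ToInt(enc2utf8(key))
  # FNV-1a variant folded to 27 bits so the multiply stays exact in doubles
  h <- 21661
  for (b in bytes) {
    h <- bitwXor(as.integer(h), as.integer(b))
    h <- (h * 16777619) %% 134217728
  }
  as.integer(h)
}

child_seed <- function(master_seed, ...) {
  key <- paste(c(master_seed, ...), collapse = "\x1f")
  stable_hash31(key)
}

#' First (interpolated) time a series crosses a level from below
#'
#' Returns NA when the series never reaches the level. When the first sample
#' already is at/above the level the first time is returned.
#' @noRd
first_crossing_time <- function(times, values, level) {
  at <- which(values >= level)
  if (length(at) == 0L) return(NA_real_)
  i <- at[1L]
  if (i == 1L) return(times[1L])
  # linear interpolation between the bracketing samples
  t0 <- times[i - 1L]; t1 <- times[i]
  v0 <- values[i - 1L]; v1 <- values[i]
  if (v1 == v0) return(t1)
  t0 + (level - v0) / (v1 - v0) * (t1 - t0)
}

#' Deterministic hash of a configuration object for run manifests
#' @noRd
config_hash <- function(x) {
  key <- paste(deparse(x, control = c("keepNA", "keepInteger", "showAttributes")),
               collapse = "\n")
  sprintf("%08x", stable_hash31(key))
}

standard_error <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2L) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}
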