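#' Single-cell trajectory container
#'
#' A `cell_trajectory` holds one cell's sampled fluorescence time series
#' (SHR reporter / nuclear-marker ratio, optionally SCR), its nuclear-size
#' series, the division events observed during the timecourse, and a
#' censoring flag. Times are hours from dexamethasone induction (or from
#' observation start for native lines), nominally sampled every 0.25 h.
#' Observation is truncated at the formative division when one occurs, so a
#' trajectory carries at most one formative division and it is the last event.
#'
#' @param cell_id,root_id Opaque identifiers.
#' @param times Strictly increasing numeric vector, hours.
#' @param shr Non-negative reporter/nuclear-marker intensity ratio, one value
#'   per timepoint.
#' @param scr Optional SCR series with the same semantics.
#' @param nuclear_size Optional positive nuclear size series, arbitrary units.
#' @param divisions Data frame with columns `time` (hours) and `orientation`
#'   (`"formative"` or `"proliferative"`), possibly empty.
#' @param censored Logical; `TRUE` when observation ended without a formative
#'   division.
#' @param dataset One of `"confocal"`, `"lightsheet"`, `"native"`.
#' @param dex_dose Dexamethasone dose in uM (`NA` for native lines).
#' @return An object of class `cell_trajectory`.
#' @export
cell_trajectory <- function(cell_id, root_id, times, shr,
                            scr = NULL, nuclear_size = NULL,
                            divisions = empty_divisions(),
                            censored = TRUE,
                            dataset = c("native", "confocal", "lightsheet"),
                            dex_dose = NA_real_) {
  dataset <- match.arg(dataset)
  times <- as.numeric(times)
  n <- length(times)
  assert_that(n >= 1L, "trajectory must have at least one timepoint")
  if (is.unsorted(times, strictly = TRUE)) {
    abort_shrscr(sprintf("times not strictly increasing for cell '%s'", cell_id),
                 "shrscr_validation_error")
  }
  check_series <- function(x, name, positive = FALSE) {
    if (is.null(x)) return(NULL)
    assert_that(length(x) == n,
                sprintf("'%s' length differs from times for cell '%s'", name, cell_id),
                "shrscr_validation_error")
    bad <- if (positive) any(x <= 0, na.rm = TRUE) else any(x < 0, na.rm = TRUE)
    if (bad) {
      abort_shrscr(sprintf("negative or non-positive '%s' values for cell '%s'",
                           name, cell_id), "shrscr_validation_error")
    }
    as.numeric(x)
  }
  shr <- check_series(shr, "shr")
  scr <- check_series(scr, "scr")
  nuclear_size <- check_series(nuclear_size, "nuclear_size", positive = TRUE)

  divisions <- as.data.frame(divisions)
  if (nrow(divisions)) {
    assert_that(all(c("time", "orientation") %in% names(divisions)),
                "divisions need columns 'time' and 'orientation'")
    assert_that(all(divisions$orientation %in% c("formative", "proliferative")),
                sprintf("invalid division orientation for cell '%s'", cell_id),
                "shrscr_validation_error")
    divisions <- divisions[order(divisions$time), , drop = FALSE]
    assert_that(all(divisions$time >= times[1L] & divisions$time <= times[n]),
                sprintf("division outside observed span for cell '%s'", cell_id),
                "shrscr_validation_error")
    n_form <- sum(divisions$orientation == "formative")
    assert_that(n_form <= 1L,
                sprintf("more than one formative division for cell '%s'", cell_id),
                "shrscr_validation_error")
    if (n_form == 1L) {
      assert_that(divisions$orientation[nrow(divisions)] == "formative",
                  sprintf("formative division is not the last event for cell '%s'",
                          cell_id), "shrscr_validation_error")
      censored <- FALSE
    }
  }
  structure(
    list(cell_id = as.character(cell_id), root_id = as.character(root_id),
         dataset = dataset, dex_dose = dex_dose,
         times = times, shr = shr, scr = scr, nuclear_size = nuclear_size,
         divisions = divisions, censored = isTRUE(censored)),
    class = "cell_trajectory")
}

empty_divisions <- function() {
  data.frame(time = numeric(0), orientation = character(0),
             stringsAsFactors = FALSE)
}

#' @export
print.cell_trajectory <- function(x, ...) {
  cat(sprintf("<cell_trajectory %s/%s: %d timepoints, %.2f-%.2f h, %d division(s)%s>\n",
              x$root_id, x$cell_id, length(x$times),
              min(x$times), max(x$times), nrow(x$divisions),
              if (x$censored) ", censored" else ""))
  invisible(x)
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat(sprintf("<trajectory_set: %d cells from %d root(s)>\n",
              length(x), length(unique(vapply(x, `[[`, "", "root_id")))))
  invisible(x)
}

#' Column mapping for long-format trajectory tables
#'
#' Maps the package's canonical column roles onto arbitrary file headers so
#' exports of supplementary spreadsheets can be ingested without editing.
#' Roles `scr`, `nuclear_size`, `event`, `orientation`, `dataset` and
#' `dex_dose` are optional and may be set to `NULL` when absent from the file.
#'
#' @param root_id,cell_id,time,shr,scr,nuclear_size,event,orientation,dataset,dex_dose
#'   Column names in the input file for each role.
#' @return A named list usable as the `schema` argument of
#'   [load_trajectories()].
#' @export
trajectory_schema <- function(root_id = "root_id", cell_id = "cell_id",
                              time = "time_h", shr = "shr", scr = "scr",
                              nuclear_size = "nuclear_size",
                              event = "event", orientation = "orientation",
                              dataset = NULL, dex_dose = NULL) {
  list(root_id = root_id, cell_id = cell_id, time = time, shr = shr,
       scr = scr, nuclear_size = nuclear_size, event = event,
       orientation = orientation, dataset = dataset, dex_dose = dex_dose)
}

#' Load single-cell trajectories from a long-format CSV/TSV table
#'
#' Expects one row per (cell, timepoint). Rows are grouped by
#' (root, cell) and sorted by time; duplicated (cell, time) rows, negative
#' intensities and missing mapped columns are rejected with informative
#' errors. Division events are taken from rows whose event column is
#' non-empty, with the orientation column giving the division plane.
#'
#' @param path Path to a `.csv` or `.tsv`/`.txt` file.
#' @param schema A [trajectory_schema()] mapping file columns to roles.
#' @return A list of [cell_trajectory()] objects (class `trajectory_set`).
#' @export
load_trajectories <- function(path, schema = trajectory_schema()) {
  assert_that(file.exists(path), sprintf("file not found: %s", path),
              "shrscr_path_error")
  sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("root_id", "cell_id", "time", "shr")
  for (role in required) {
    col <- schema[[role]]
    if (is.null(col) || !col %in% names(tab)) {
      abort_shrscr(sprintf("required column '%s' (role '%s') missing from %s",
                           schema[[role]] %||% "<unmapped>", role, path),
                   "shrscr_schema_error")
    }
  }
  has <- function(role) !is.null(schema[[role]]) && schema[[role]] %in% names(tab)
  tab$.root <- as.character(tab[[schema$root_id]])
  tab$.cell <- as.character(tab[[schema$cell_id]])
  split_key <- paste(tab$.root, tab$.cell, sep = "\x1f")
  groups <- split(tab, factor(split_key, levels = unique(split_key)))

  trajs <- lapply(groups, function(g) {
    g <- g[order(g[[schema$time]]), , drop = FALSE]
    tt <- as.numeric(g[[schema$time]])
    if (anyDuplicated(tt)) {
      abort_shrscr(sprintf("duplicated (cell, time) rows for cell '%s'", g$.cell[1L]),
                   "shrscr_validation_error")
    }
    divisions <- empty_divisions()
    if (has("event")) {
      ev <- g[[schema$event]]
      is_div <- !is.na(ev) & ev != "" & ev != "none" & ev != "0" & ev != "FALSE"
      if (any(is_div)) {
        assert_that(has("orientation"),
                    "division events present but no orientation column mapped",
                    "shrscr_schema_error")
        divisions <- data.frame(time = tt[is_div],
                                orientation = as.character(g[[schema$orientation]][is_div]),
                                stringsAsFactors = FALSE)
      }
    }
    cell_trajectory(
      cell_id = g$.cell[1L], root_id = g$.root[1L],
      times = tt, shr = as.numeric(g[[schema$shr]]),
      scr = if (has("scr")) as.numeric(g[[schema$scr]]) else NULL,
      nuclear_size = if (has("nuclear_size")) as.numeric(g[[schema$nuclear_size]]) else NULL,
      divisions = divisions,
      dataset = if (has("dataset")) g[[schema$dataset]][1L] else "native",
      dex_dose = if (has("dex_dose")) as.numeric(g[[schema$dex_dose]][1L]) else NA_real_)
  })
  names(trajs) <- vapply(trajs, function(x) paste(x$root_id, x$cell_id, sep = "/"), "")
  structure(trajs, class = "trajectory_set")
}

#' Write trajectories back to the canonical long-format CSV
#'
#' Inverse of [load_trajectories()] with the default schema.
#' @param trajs A list of [cell_trajectory()] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectories_csv <- function(trajs, path) {
  rows <- lapply(trajs, function(tr) {
    n <- length(tr$times)
    ev <- character(n); ori <- character(n)
    if (nrow(tr$divisions)) {
      idx <- vapply(tr$divisions$time, function(t) which.min(abs(tr$times - t)), 1L)
      ev[idx] <- "division"
      ori[idx] <- tr$divisions$orientation
    }
    data.frame(root_id = tr$root_id, cell_id = tr$cell_id, time_h = tr$times,
               shr = tr$shr,
               scr = if (is.null(tr$scr)) NA_real_ else tr$scr,
               nuclear_size = if (is.null(tr$nuclear_size)) NA_real_ else tr$nuclear_size,
               event = ev, orientation = ori,
               dataset = tr$dataset, dex_dose = tr$dex_dose,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Centered moving-average smoothing
#'
#' Boundary windows shrink symmetrically-as-possible (the window is clipped to
#' the series), so the output has the same length as the input and no padding
#' value is invented. `window = 1` is the identity.
#'
#' @param series Numeric vector.
#' @param window Odd positive integer, number of frames (default 5, i.e. 75
#'   min at 15-min sampling).
#' @return Smoothed numeric vector of the same length.
#' @export
smooth_series <- function(series, window = 5L) {
  assert_that(length(window) == 1L && window >= 1 && window %% 2 == 1,
              "'window' must be a positive odd integer")
  n <- length(series)
  assert_that(n >= 1L, "'series' must be non-empty")
  if (window == 1L || n == 1L) return(series)
  h <- (window - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    mean(series[max(1L, i - h):min(n, i + h)])
  }, numeric(1))
}

#' Normalize a series to a quantile of a reference series
#'
#' Divides every value by the `q`-quantile of `reference` computed with the
#' linear-interpolation convention (`stats::quantile(type = 7)`). The
#' convention is fixed because the normalization constant depends on it. With
#' `reference = series` the `q`-quantile of the output equals 1.
#'
#' @param series Numeric vector to rescale.
#' @param q Quantile probability, default 0.90.
#' @param reference Series whose quantile sets the scale; defaults to
#'   `series` itself, but is typically the pooled values of one channel
#'   across the cells of a root.
#' @return Rescaled numeric vector.
#' @export
normalize_to_quantile <- function(series, q = 0.90, reference = series) {
  assert_that(length(reference) > 0, "'reference' must be non-empty")
  divisor <- unname(stats::quantile(reference, probs = q, type = 7, na.rm = TRUE))
  if (!is.finite(divisor) || divisor <= 0) {
    abort_shrscr(sprintf("q-quantile of reference is %.3g; normalization degenerate",
                         divisor), "shrscr_degenerate_normalization_error")
  }
  series / divisor
}

#' Normalize one channel across a set of trajectories
#'
#' Applies [normalize_to_quantile()] with the reference pooled at a chosen
#' scope: per root (default; preserves relative levels between the cells of
#' one root, which the threshold analysis depends on), per cell, or across
#' the whole dataset.
#'
#' @param trajs A list of [cell_trajectory()] objects.
#' @param channel `"shr"` or `"scr"`.
#' @param scope `"root"`, `"cell"` or `"dataset"`.
#' @param q Quantile probability, default 0.90.
#' @return The trajectory list with the channel rescaled in place.
#' @export
normalize_trajectories <- function(trajs, channel = c("shr", "scr"),
                                   scope = c("root", "cell", "dataset"),
                                   q = 0.90) {
  channel <- match.arg(channel)
  scope <- match.arg(scope)
  keep <- vapply(trajs, function(tr) !is.null(tr[[channel]]), TRUE)
  assert_that(any(keep), sprintf("no trajectory carries channel '%s'", channel))
  pool_of <- function(tr) {
    switch(scope,
      cell = tr[[channel]],
      root = unlist(lapply(trajs[keep], function(o)
        if (o$root_id == tr$root_id) o[[channel]] else NULL)),
      dataset = unlist(lapply(trajs[keep], `[[`, channel)))
  }
  out <- lapply(trajs, function(tr) {
    if (!is.null(tr[[channel]])) {
      tr[[channel]] <- normalize_to_quantile(tr[[channel]], q = q,
                                             reference = pool_of(tr))
    }
    tr
  })
  class(out) <- class(trajs)
  out
}

#' Average normalized trajectories on a common time grid
#'
#' Each series is linearly interpolated onto the grid within its own observed
#' span only (no extrapolation); cells whose observation ended (for example at
#' a formative division) stop contributing, so `n_at_t` can decrease along the
#' grid. Gridpoints covered by zero cells are dropped with a warning.
#'
#' @param series_list List of `list(times =, values =)` pairs, or a list of
#'   [cell_trajectory()] objects combined with `channel`.
#' @param grid Numeric time grid, hours.
#' @param channel Channel to extract when `series_list` holds trajectories.
#' @return A `mean_trajectory`: data frame with columns `time`, `mean`,
#'   `sem`, `n`.
#' @export
average_trajectories <- function(series_list, grid, channel = "shr") {
  assert_that(length(series_list) >= 1L, "need at least one trajectory")
  series_list <- lapply(series_list, function(s) {
    if (inherits(s, "cell_trajectory")) {
      assert_that(!is.null(s[[channel]]),
                  sprintf("trajectory lacks channel '%s'", channel))
      list(times = s$times, values = s[[channel]])
    } else s
  })
  vals <- vapply(series_list, function(s) {
    inside <- grid >= min(s$times) & grid <= max(s$times)
    out <- rep(NA_real_, length(grid))
    if (any(inside)) {
      out[inside] <- stats::approx(s$times, s$values, xout = grid[inside],
                                   ties = "ordered")$y
    }
    out
  }, numeric(length(grid)))
  vals <- matrix(vals, nrow = length(grid))
  n_at_t <- rowSums(!is.na(vals))
  if (any(n_at_t == 0L)) {
    warning(sprintf("%d gridpoint(s) covered by no cell; dropped", sum(n_at_t == 0L)))
  }
  keep <- n_at_t > 0L
  m <- rowMeans(vals, na.rm = TRUE)[keep]
  s <- apply(vals, 1L, function(r) {
    r <- r[!is.na(r)]
    if (length(r) < 2L) 0 else stats::sd(r) / sqrt(length(r))
  })[keep]
  structure(data.frame(time = grid[keep], mean = m, sem = s, n = n_at_t[keep]),
            class = c("mean_trajectory", "data.frame"))
}

#' Segment a trajectory into cell cycles
#'
#' Observation start, every division, and observation end act as boundaries;
#' each inter-division interval becomes one `cell_cycle_segment` carrying the
#' slice of every series, the per-segment min-max-normalized nuclear size
#' (`norm_size`), and an outcome label: the orientation of the division that
#' ends the segment, or `"censored"` for a trailing segment that ends with
#' the observation. Segments with fewer than `min_points` timepoints are
#' dropped (a division falling exactly on a sampled frame would otherwise
#' produce empty slivers).
#'
#' @param traj A [cell_trajectory()] with a `nuclear_size` series.
#' @param min_points Minimum timepoints per segment, default 2.
#' @return List of `cell_cycle_segment` objects, ordered, non-overlapping.
#' @export
segment_cycles <- function(traj, min_points = 2L) {
  if (is.null(traj$nuclear_size)) {
    abort_shrscr(sprintf("trajectory '%s' has no nuclear_size series", traj$cell_id),
                 "shrscr_feature_unavailable_error")
  }
  t0 <- traj$times[1L]; t1 <- traj$times[length(traj$times)]
  div_t <- traj$divisions$time
  bounds <- unique(c(t0, div_t, t1))
  outcomes <- c(traj$divisions$orientation,
                if (length(div_t) == 0L || max(div_t) < t1) "censored")
  segs <- list()
  for (k in seq_len(length(bounds) - 1L)) {
    lo <- bounds[k]; hi <- bounds[k + 1L]
    # a timepoint at a division boundary belongs to the cycle it ends
    sel <- if (k == 1L) traj$times >= lo & traj$times <= hi
           else traj$times > lo & traj$times <= hi
    if (sum(sel) < min_points) next
    size <- traj$nuclear_size[sel]
    rng <- range(size)
    norm_size <- if (diff(rng) > 0) (size - rng[1L]) / diff(rng) else rep(0, sum(sel))
    segs[[length(segs) + 1L]] <- structure(
      list(cell_id = traj$cell_id, root_id = traj$root_id,
           index = length(segs) + 1L, span = c(lo, hi),
           times = traj$times[sel],
           shr = traj$shr[sel],
           scr = if (is.null(traj$scr)) NULL else traj$scr[sel],
           nuclear_size = size, norm_size = norm_size,
           outcome = outcomes[k]),
      class = "cell_cycle_segment")
  }
  segs
}

#' @export
print.cell_cycle_segment <- function(x, ...) {
  cat(sprintf("<cell_cycle_segment %s/%s #%d: [%.2f, %.2f] h, %s>\n",
              x$root_id, x$cell_id, x$index, x$span[1L], x$span[2L], x$outcome))
  invisible(x)
}

#' Initial nuclear size of a trajectory, normalized within the cell
#'
#' The first nuclear-size value min-max rescaled over the cell's whole
#' observed series; a proxy for cell-cycle position at observation start.
#' @param traj A [cell_trajectory()] with `nuclear_size`.
#' @return Scalar in `[0, 1]`.
#' @export
initial_norm_size <- function(traj) {
  assert_that(!is.null(traj$nuclear_size), "trajectory has no nuclear_size",
              "shrscr_feature_unavailable_error")
  rng <- range(traj$nuclear_size)
  if (diff(rng) == 0) return(0)
  (traj$nuclear_size[1L] - rng[1L]) / diff(rng)
}
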