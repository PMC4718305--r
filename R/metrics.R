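#' Therapeutic-window compliance metrics
#'
#' Summarises how well a simulated concentration series stays inside a
#' [therapeutic_window()] over an evaluation interval. Crossing times are
#' located by bisection on the exact propagator within the grid interval
#' that brackets each sign change (tolerance 1e-4 min), so all durations are
#' computed from crossing times rather than by counting grid points and are
#' independent of the simulation `grid_step`.
#'
#' @param series A `concentration_series` from [simulate_regimen()].
#' @param window A [therapeutic_window()]; its `reference` field selects the
#'   concentration that is compared to the bounds.
#' @param eval_start,eval_end Evaluation interval in minutes (defaults: the
#'   full simulated range).
#' @return An object of class `window_metrics` with fields:
#'   `first_below_mec` — time of the first downward crossing of the lower
#'   bound after the first dose event (NA if none); `first_below_mec_rel` —
#'   the same, relative to the first dose event; `time_below_mec`,
#'   `time_above_upper` — total minutes outside the window within the
#'   evaluation interval; `c_max`, `t_cmax` — peak reference concentration
#'   and its time; `undertreated_intervals` — data frame of maximal
#'   sub-MEC intervals (`start`, `end`); plus the window and interval used.
#' @examples
#' ser <- simulate_regimen(scenario_regimen("group_a"), t_end = 120)
#' window_metrics(ser, eval_start = 0, eval_end = 120)
#' @export
window_metrics <- function(series, window = therapeutic_window(),
                           eval_start = NULL, eval_end = NULL) {
  stopifnot(inherits(series, "concentration_series"),
            inherits(window, "therapeutic_window"))
  tt <- series$times
  if (is.null(eval_start)) eval_start <- tt[1]
  if (is.null(eval_end)) eval_end <- tt[length(tt)]
  if (eval_start >= eval_end)
    stop("window_metrics: degenerate evaluation interval", call. = FALSE)
  if (eval_start < tt[1] - 1e-9 || eval_end > tt[length(tt)] + 1e-9)
    stop("window_metrics: evaluation interval outside the simulated range", call. = FALSE)

  ref_col <- if (window$reference == "plasma") "cp" else "ce"
  refv <- series[[ref_col]]

  below <- crossing_set(series, refv, window$mec, eval_start, eval_end,
                        side = "below")
  above <- crossing_set(series, refv, window$upper, eval_start, eval_end,
                        side = "above")

  first_dose <- first_dose_time(series)
  down <- below$down_crossings
  down <- down[!is.na(first_dose) & down > first_dose + 1e-9]
  first_below <- if (length(down)) down[1] else NA_real_

  pk <- peak_reference(series, refv, eval_start, eval_end,
                       plasma = window$reference == "plasma")

  und <- below$intervals
  structure(list(first_below_mec = first_below,
                 first_below_mec_rel = first_below - first_dose,
                 time_below_mec = sum(und$end - und$start),
                 time_above_upper = sum(above$intervals$end - above$intervals$start),
                 c_max = pk$c_max, t_cmax = pk$t_cmax,
                 undertreated_intervals = und,
                 first_dose_time = first_dose,
                 window = window, eval_start = eval_start, eval_end = eval_end),
            class = "window_metrics")
}

#' @export
print.window_metrics <- function(x, ...) {
  cat(sprintf("Window metrics on [%g, %g] min (%s reference, window [%g, %g] ng/mL)\n",
              x$eval_start, x$eval_end, gsub("_", "-", x$window$reference),
              x$window$mec, x$window$upper))
  if (is.na(x$first_below_mec)) {
    cat("  no downward MEC crossing after the first dose\n")
  } else {
    cat(sprintf("  first below MEC: t = %.3f min (%.3f min after the first dose)\n",
                x$first_below_mec, x$first_below_mec_rel))
  }
  cat(sprintf("  time below MEC: %.3f min; time above upper bound: %.3f min\n",
              x$time_below_mec, x$time_above_upper))
  cat(sprintf("  peak %.4g ng/mL at t = %.3f min\n", x$c_max, x$t_cmax))
  if (nrow(x$undertreated_intervals)) {
    cat("  undertreated intervals (min):\n")
    for (i in seq_len(nrow(x$undertreated_intervals)))
      cat(sprintf("    [%.3f, %.3f]\n", x$undertreated_intervals$start[i],
                  x$undertreated_intervals$end[i]))
  }
  invisible(x)
}

#' @export
as.list.window_metrics <- function(x, ...) {
  list(reference = x$window$reference, mec = x$window$mec, upper = x$window$upper,
       eval_start = x$eval_start, eval_end = x$eval_end,
       first_below_mec = x$first_below_mec,
       first_below_mec_rel = x$first_below_mec_rel,
       time_below_mec = x$time_below_mec,
       time_above_upper = x$time_above_upper,
       c_max = x$c_max, t_cmax = x$t_cmax,
       undertreated_intervals = x$undertreated_intervals)
}

first_dose_time <- function(series) {
  sched <- series$events
  cand <- c(sched$boluses$time,
            sched$rate_steps$time[sched$rate_steps$rate_ug_min > 0])
  if (length(cand)) min(cand) else NA_real_
}

# exact reference concentration at time t within grid interval i (no events
# strictly inside an interval); vectorised over t for optimize()
interval_value <- function(series, i, t, plasma) {
  vapply(t, function(ti) {
    dt <- ti - series$times[i]
    if (dt <= 0) {
      x <- series$states[i, ]
    } else {
      x <- step_vector(series$states[i, ],
                       transition_matrix(series$params, dt), series$rates[i])
    }
    if (plasma) x[1] / series$params$v_central else x[4]
  }, 0)
}

# All crossings of `bound` by the reference concentration on [from, to].
# side = "below": intervals where ref < bound (and their entry times as
# down-crossings); side = "above": intervals where ref > bound.
crossing_set <- function(series, refv, bound, from, to, side, tol = 1e-4) {
  tt <- series$times
  plasma <- identical(refv, series$cp)
  sgn <- function(v) if (side == "below") v < bound else v > bound

  i0 <- max(findInterval(from, tt), 1L)
  i1 <- max(findInterval(to, tt), 1L)

  val_at <- function(t) {
    i <- max(findInterval(t, tt), 1L)
    if (abs(tt[i] - t) <= 1e-12) refv[i] else interval_value(series, i, t, plasma)
  }

  # plasma jumps (upward) only at bolus instants; ce is continuous, so the
  # left limit at a stored point differs from the stored value only there
  bol_idx <- if (plasma && nrow(series$events$boluses)) {
    match_times(series$events$boluses$time, tt)
  } else integer(0)

  crossings <- numeric(0)   # times where the indicator switches
  states0 <- sgn(val_at(from))
  # walk grid intervals overlapping [from, to]
  for (i in i0:i1) {
    a <- max(tt[i], from)
    b <- if (i < length(tt)) min(tt[i + 1], to) else to
    if (b <= a + 1e-12) next
    va <- if (abs(a - tt[i]) <= 1e-12) refv[i] else interval_value(series, i, a, plasma)
    at_break <- i < length(tt) && abs(b - tt[i + 1]) <= 1e-12
    # left limit at b excludes any bolus applied at b itself
    vb_left <- if (at_break && !((i + 1L) %in% bol_idx)) refv[i + 1]
               else interval_value(series, i, b, plasma)
    if (xor(sgn(va), sgn(vb_left))) {
      crossings <- c(crossings, bisect_crossing(series, i, a, b, bound, plasma, tol))
    }
    # jump at the right endpoint (bolus): an instantaneous switch at exactly b
    if (at_break && xor(sgn(vb_left), sgn(refv[i + 1]))) crossings <- c(crossings, b)
  }
  crossings <- sort(crossings)

  # assemble maximal intervals where the indicator is TRUE
  bounds <- c(from, crossings, to)
  starts <- numeric(0); ends <- numeric(0); down <- numeric(0)
  state <- states0
  for (k in seq_len(length(bounds) - 1L)) {
    if (state) {
      starts <- c(starts, bounds[k]); ends <- c(ends, bounds[k + 1])
      if (side == "below" && k > 1L) down <- c(down, bounds[k])
    }
    state <- !state
  }
  # merge zero-length artefacts
  keep <- ends - starts > 1e-9
  list(intervals = data.frame(start = starts[keep], end = ends[keep]),
       down_crossings = down)
}

bisect_crossing <- function(series, i, a, b, bound, plasma, tol) {
  fa <- interval_value(series, i, a, plasma) - bound
  while (b - a > tol) {
    m <- (a + b) / 2
    fm <- interval_value(series, i, m, plasma) - bound
    if ((fa <= 0) == (fm <= 0)) { a <- m; fa <- fm } else b <- m
  }
  (a + b) / 2
}

# Grid-independent peak: take the grid argmax, refine by optimize() over the
# two adjacent smooth intervals, and compare with stored breakpoint values
# (a plasma peak can sit exactly at a bolus instant).
peak_reference <- function(series, refv, from, to, plasma) {
  tt <- series$times
  in_win <- tt >= from - 1e-12 & tt <= to + 1e-12
  idx <- which(in_win)
  j <- idx[which.max(refv[idx])]
  best_c <- refv[j]; best_t <- tt[j]
  for (i in c(j - 1L, j)) {
    if (i < 1L || i >= length(tt)) next
    a <- max(tt[i], from); b <- min(tt[i + 1], to)
    if (b <= a) next
    op <- stats::optimize(function(t) interval_value(series, i, t, plasma),
                          lower = a, upper = b, maximum = TRUE, tol = 1e-6)
    if (op$objective > best_c) { best_c <- op$objective; best_t <- op$maximum }
  }
  list(c_max = best_c, t_cmax = best_t)
}
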