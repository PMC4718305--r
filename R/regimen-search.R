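#' Candidate space for basal step-down schedules
#'
#' Describes the regimens examined by [search_regimen()]: every combination
#' of an initial basal rate, a step-down time and a subsequent basal rate,
#' drawn from `candidate_rates` x `step_down_times` x `candidate_rates`, on
#' top of fixed loading events and fixed PCA demand settings. This mirrors
#' the design step of a model-based PCA scheme: pick the cheapest basal
#' taper that keeps the concentration inside the therapeutic window without
#' relying on demand boluses.
#'
#' @param candidate_rates Basal rates to consider, ug/h (>= 0).
#' @param step_down_times Times (minutes after the end of surgery) at which
#'   the basal rate may be reprogrammed.
#' @param demand_dose,lockout Fixed PCA settings carried by every candidate
#'   (demands are *not* simulated during the search).
#' @param loading_events Fixed events preceding the basal schedule; the
#'   default is the model-based scenario's loading infusion, 50 ug over the
#'   10 min before the end of surgery (300 ug/h on `[-10, 0)`).
#' @param horizon Horizon in minutes over which the total scheduled dose
#'   (the search objective) is accounted.
#' @return An object of class `search_space`.
#' @examples
#' search_space(candidate_rates = seq(0, 50, by = 5), step_down_times = 60)
#' @export
search_space <- function(candidate_rates, step_down_times,
                         demand_dose = 10, lockout = 15,
                         loading_events = list(infusion_segment(-10, 0, 300)),
                         horizon = 2880) {
  if (!is.numeric(candidate_rates) || length(candidate_rates) == 0L ||
      any(candidate_rates < 0))
    stop("search_space: 'candidate_rates' must be non-negative ug/h values", call. = FALSE)
  if (!is.numeric(step_down_times) || length(step_down_times) == 0L ||
      is.unsorted(step_down_times, strictly = TRUE))
    stop("search_space: 'step_down_times' must be increasing times", call. = FALSE)
  structure(list(candidate_rates = as.numeric(candidate_rates),
                 step_down_times = as.numeric(step_down_times),
                 demand_dose = demand_dose, lockout = lockout,
                 loading_events = loading_events, horizon = horizon),
            class = "search_space")
}

candidate_regimen <- function(space, initial, step_t, subsequent) {
  basal <- list()
  if (initial > 0) basal <- c(basal, list(infusion_segment(0, step_t, initial)))
  if (subsequent > 0) basal <- c(basal, list(infusion_segment(step_t, Inf, subsequent)))
  regimen(name = sprintf("basal_%g_to_%g_at_%g", initial, subsequent, step_t),
          preop_events = space$loading_events,
          pca = pca_program(space$demand_dose, space$lockout, basal = basal),
          policy = demand_policy("none"))
}

#' Search basal step-down schedules for window compliance
#'
#' Exhaustively evaluates every candidate of a [search_space()] under the
#' deterministic no-demand scenario (demand boluses would only raise the
#' concentration, so feasibility without them is the conservative case).
#' A candidate is feasible when the reference concentration neither falls
#' below the window's lower bound nor exceeds its upper bound anywhere in
#' `constraint_window`. Among feasible candidates the one with the smallest
#' total scheduled dose over the space's horizon wins; ties are broken by
#' lower peak reference concentration, then by enumeration order
#' (initial rate, step-down time, subsequent rate — all ascending). If no
#' candidate is feasible the least-violating one (smallest total time
#' outside the window) is returned with `feasible = FALSE`.
#'
#' @param space A [search_space()].
#' @param params A [pk_parameters()].
#' @param window A [therapeutic_window()].
#' @param constraint_window Length-2 numeric, the interval (minutes) on which
#'   window compliance is enforced.
#' @param grid_step Simulation grid step used for the evaluations (crossing
#'   detection itself is grid-independent).
#' @return An object of class `search_result`: `ranked` (one row per
#'   candidate, best first), `selected` (the winning [regimen()]),
#'   `selected_metrics` (its [window_metrics()]), and `feasible`.
#' @examples
#' \donttest{
#' sp <- search_space(seq(0, 30, by = 10), step_down_times = 60, horizon = 240)
#' search_regimen(sp, constraint_window = c(0, 60))
#' }
#' @export
search_regimen <- function(space, params = pk_parameters(),
                           window = therapeutic_window(),
                           constraint_window = c(0, 60), grid_step = 0.5) {
  stopifnot(inherits(space, "search_space"), inherits(params, "pk_parameters"),
            inherits(window, "therapeutic_window"))
  if (length(constraint_window) != 2L || diff(constraint_window) <= 0)
    stop("search_regimen: 'constraint_window' must be an increasing pair", call. = FALSE)

  grid <- expand.grid(initial = space$candidate_rates,
                      step_t = space$step_down_times,
                      subsequent = space$candidate_rates)
  grid <- grid[order(grid$initial, grid$step_t, grid$subsequent), , drop = FALSE]
  if (nrow(grid) == 0L) stop("search_regimen: empty search space", call. = FALSE)

  t_sim_start <- min(-10, constraint_window[1],
                     vapply(space$loading_events, function(e)
                       if (inherits(e, "bolus_event")) e$t else e$t_start, 0))
  t_sim_end <- constraint_window[2]

  eval_one <- function(initial, step_t, subsequent) {
    r <- candidate_regimen(space, initial, step_t, subsequent)
    ser <- simulate_regimen(r, params, t_start = t_sim_start, t_end = t_sim_end,
                            grid_step = grid_step)
    m <- window_metrics(ser, window, constraint_window[1], constraint_window[2])
    # dose objective over the full horizon is arithmetic, no long simulation
    sched <- expand_regimen(r, horizon = space$horizon, t_start = t_sim_start)
    data.frame(initial_rate = initial, step_down_time = step_t,
               subsequent_rate = subsequent,
               feasible = m$time_below_mec <= 1e-6 && m$time_above_upper <= 1e-6,
               time_below_mec = m$time_below_mec,
               time_above_upper = m$time_above_upper,
               peak = m$c_max,
               total_dose = sched$scheduled_dose)
  }

  rows <- do.call(rbind, Map(eval_one, grid$initial, grid$step_t, grid$subsequent))
  rows$violation <- rows$time_below_mec + rows$time_above_upper
  ord <- order(!rows$feasible, ifelse(rows$feasible, rows$total_dose, rows$violation),
               rows$peak, rows$initial_rate, rows$step_down_time, rows$subsequent_rate)
  ranked <- rows[ord, , drop = FALSE]
  rownames(ranked) <- NULL

  best <- ranked[1, ]
  sel <- candidate_regimen(space, best$initial_rate, best$step_down_time,
                           best$subsequent_rate)
  ser <- simulate_regimen(sel, params, t_start = t_sim_start, t_end = t_sim_end,
                          grid_step = grid_step)
  structure(list(ranked = ranked, selected = sel,
                 selected_metrics = window_metrics(ser, window,
                                                   constraint_window[1],
                                                   constraint_window[2]),
                 feasible = isTRUE(best$feasible),
                 constraint_window = constraint_window,
                 window = window),
            class = "search_result")
}

#' @export
print.search_result <- function(x, ...) {
  cat(sprintf("Regimen search over %d candidates, compliance on [%g, %g] min\n",
              nrow(x$ranked), x$constraint_window[1], x$constraint_window[2]))
  if (x$feasible) {
    b <- x$ranked[1, ]
    cat(sprintf("  selected: %g ug/h stepping to %g ug/h at t = %g min (total %g ug)\n",
                b$initial_rate, b$subsequent_rate, b$step_down_time, b$total_dose))
  } else {
    cat(sprintf("  no feasible candidate; least violating spends %.3f min outside the window\n",
                x$ranked$violation[1]))
  }
  print(utils::head(x$ranked, 5))
  invisible(x)
}
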