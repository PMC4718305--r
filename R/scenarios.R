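#' Built-in study scenarios
#'
#' The two postoperative-analgesia dosing programs compared by the package's
#' worked examples, both starting 10 min before the end of surgery (t = 0):
#'
#' * `"group_a"` — conventional demand-only PCA: a 50 ug intravenous bolus at
#'   t = -10 min, then PCA with a 10 ug demand bolus, a 10-min lockout and no
#'   basal infusion.
#' * `"group_b"` — model-based PCA: 50 ug loaded as a zero-order infusion
#'   over the 10 min before the end of surgery (300 ug/h on `[-10, 0)`), then
#'   PCA with a 10 ug demand bolus, a 15-min lockout and a basal infusion of
#'   20 ug/h for the first hour stepped down to 10 ug/h thereafter.
#'
#' Both ship with demand policy `"none"`: the deterministic base case used
#' for the concentration-curve figures. Rescue boluses are not included by
#' default; add them via the `rescue_events` field if needed.
#'
#' @param name Scenario name, one of [scenario_names()].
#' @return A [regimen()].
#' @examples
#' scenario_regimen("group_b")
#' @export
scenario_regimen <- function(name) {
  if (!is.character(name) || length(name) != 1L || !(name %in% scenario_names()))
    stop("unknown scenario '", name, "'; valid names: ",
         paste(scenario_names(), collapse = ", "), call. = FALSE)
  switch(name,
    group_a = regimen(
      name = "group_a",
      preop_events = list(bolus_event(-10, 50)),
      pca = pca_program(demand_dose = 10, lockout = 10),
      policy = demand_policy("none")
    ),
    group_b = regimen(
      name = "group_b",
      preop_events = list(infusion_segment(-10, 0, 300)),
      pca = pca_program(demand_dose = 10, lockout = 15,
                        basal = list(infusion_segment(0, 60, 20),
                                     infusion_segment(60, Inf, 10))),
      policy = demand_policy("none")
    ))
}

#' @rdname scenario_regimen
#' @export
scenario_names <- function() c("group_a", "group_b")

#' Read and write regimen JSON configs
#'
#' The schema is a single JSON object:
#' \preformatted{
#' {
#'   "name": "group_b",
#'   "events": [
#'     {"type": "bolus", "t": -10, "dose": 50},
#'     {"type": "infusion", "t_start": -10, "t_end": 0, "rate": 300}
#'   ],
#'   "pca": {
#'     "demand_dose": 10, "lockout": 15,
#'     "basal": [{"t_start": 0, "t_end": 60, "rate": 20},
#'               {"t_start": 60, "t_end": null, "rate": 10}]
#'   },
#'   "demand_policy": {"mode": "none"},
#'   "rescue": [{"t": 30, "dose": 25}]
#' }
#' }
#' Times are minutes, doses ug, rates ug/h; `"t_end": null` means open-ended.
#' `pca`, `demand_policy` and `rescue` are optional. A round trip
#' `load_regimen(save_regimen(x, path))` reproduces `x` exactly.
#'
#' @param path File path.
#' @param r A [regimen()].
#' @return `load_regimen()` returns a [regimen()]; `save_regimen()` returns
#'   `path` invisibly.
#' @export
load_regimen <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  cfg <- jsonlite::read_json(path, simplifyVector = FALSE)
  req_num <- function(obj, field, where) {
    v <- obj[[field]]
    if (is.null(v) || !is.numeric(v))
      stop(sprintf("regimen config %s: missing or non-numeric field '%s' in %s",
                   path, field, where), call. = FALSE)
    v
  }
  if (is.null(cfg$name) || !is.character(cfg$name))
    stop("regimen config ", path, ": missing 'name'", call. = FALSE)

  parse_segment <- function(e, where) {
    t_end <- if (is.null(e$t_end)) Inf else e$t_end
    infusion_segment(req_num(e, "t_start", where), t_end, req_num(e, "rate", where))
  }
  events <- lapply(seq_along(cfg$events), function(i) {
    e <- cfg$events[[i]]
    where <- sprintf("events[%d]", i)
    if (is.null(e$type)) stop("regimen config ", path, ": missing 'type' in ",
                              where, call. = FALSE)
    switch(e$type,
      bolus = bolus_event(req_num(e, "t", where), req_num(e, "dose", where)),
      infusion = parse_segment(e, where),
      stop("regimen config ", path, ": unknown event type '", e$type, "' in ",
           where, call. = FALSE))
  })

  pca <- if (is.null(cfg$pca)) pca_program() else {
    basal <- lapply(seq_along(cfg$pca$basal), function(i)
      parse_segment(cfg$pca$basal[[i]], sprintf("pca$basal[%d]", i)))
    pca_program(req_num(cfg$pca, "demand_dose", "pca"),
                req_num(cfg$pca, "lockout", "pca"), basal)
  }
  pol <- if (is.null(cfg$demand_policy)) demand_policy("none") else
    demand_policy(cfg$demand_policy$mode,
                  rate = cfg$demand_policy$rate, seed = cfg$demand_policy$seed)
  rescue <- lapply(seq_along(cfg$rescue), function(i)
    bolus_event(req_num(cfg$rescue[[i]], "t", sprintf("rescue[%d]", i)),
                req_num(cfg$rescue[[i]], "dose", sprintf("rescue[%d]", i))))
  regimen(cfg$name, preop_events = events, pca = pca, policy = pol,
          rescue_events = rescue)
}

#' @rdname load_regimen
#' @export
save_regimen <- function(r, path) {
  stopifnot(inherits(r, "regimen"))
  seg_json <- function(s) list(t_start = s$t_start,
                               t_end = if (is.finite(s$t_end)) s$t_end else NULL,
                               rate = s$rate)
  ev_json <- function(e) {
    if (inherits(e, "bolus_event")) list(type = "bolus", t = e$t, dose = e$dose)
    else c(list(type = "infusion"), seg_json(e))
  }
  out <- list(
    name = r$name,
    events = lapply(r$preop_events, ev_json),
    pca = list(demand_dose = r$pca$demand_dose, lockout = r$pca$lockout,
               basal = lapply(r$pca$basal, seg_json)),
    demand_policy = Filter(Negate(is.null), r$policy),
    rescue = lapply(r$rescue_events, function(e) list(t = e$t, dose = e$dose))
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(path)
}

#' Plot a concentration series
#'
#' Plasma concentration as a dashed line, effect-site as a solid line, a
#' horizontal line at the window's lower bound and (optionally) shading of
#' the sub-MEC ("undertreated") intervals of the reference concentration.
#'
#' @param series A `concentration_series`.
#' @param window A [therapeutic_window()] drawn on the plot.
#' @param shade_undertreated Shade intervals where the reference
#'   concentration is below the MEC.
#' @param eval_start,eval_end Interval used for the shading (defaults to the
#'   plotted range from 0 onward).
#' @param ... Passed to [graphics::plot()].
#' @return The series, invisibly.
#' @export
plot_series <- function(series, window = therapeutic_window(),
                        shade_undertreated = TRUE,
                        eval_start = NULL, eval_end = NULL, ...) {
  stopifnot(inherits(series, "concentration_series"))
  tt <- series$times
  ylim <- c(0, max(series$cp, series$ce, window$mec) * 1.05)
  graphics::plot(tt, series$cp, type = "n", ylim = ylim,
                 xlab = "time after end of surgery (min)",
                 ylab = "fentanyl concentration (ng/mL)",
                 main = series$regimen_name, ...)
  if (shade_undertreated) {
    m <- window_metrics(series, window,
                        eval_start %||% max(0, tt[1]),
                        eval_end %||% tt[length(tt)])
    ui <- m$undertreated_intervals
    if (nrow(ui))
      graphics::rect(ui$start, 0, ui$end, ylim[2],
                     col = grDevices::grey(0.9), border = NA)
  }
  graphics::abline(h = window$mec, col = "black")
  graphics::lines(tt, series$cp, lty = 2)
  graphics::lines(tt, series$ce, lty = 1, col = "red")
  graphics::legend("topright", c("plasma", "effect site", "MEC"),
                   lty = c(2, 1, 1), col = c("black", "red", "black"),
                   bty = "n")
  invisible(series)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
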