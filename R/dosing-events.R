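#' Dosing event and program constructors
#'
#' Building blocks of a dosing program: `bolus_event()` is an instantaneous
#' intravenous bolus; `infusion_segment()` a zero-order infusion at a constant
#' rate over a half-open interval `[t_start, t_end)` (`t_end = Inf` means
#' "until the end of the simulation"); `pca_program()` the pump settings of a
#' patient-controlled analgesia program (demand bolus size, lockout interval,
#' basal infusion schedule); `demand_policy()` a model of when the patient
#' presses the demand button; and `regimen()` ties them together.
#'
#' Rates are specified in ug/h, the unit pumps are programmed in; they are
#' converted to ug/min internally. Times are minutes, with 0 the end of
#' surgery (events before 0 are preoperative).
#'
#' @param t,t_start,t_end Event times in minutes.
#' @param dose Bolus dose in micrograms (>= 0).
#' @param rate Infusion rate in ug/h (>= 0); for `demand_policy`, the Poisson
#'   demand-attempt rate in attempts/h.
#' @param demand_dose PCA demand bolus in micrograms.
#' @param lockout Lockout interval in minutes (> 0): the minimum time after a
#'   *granted* demand before the next demand can be granted (pump convention;
#'   rejected attempts do not restart the clock).
#' @param basal List of `infusion_segment()`s forming the basal schedule;
#'   segments must not overlap.
#' @param mode Demand model: `"none"` (no attempts; the deterministic base
#'   case), `"worst_case"` (continuous pressing, so grants occur exactly every
#'   lockout interval) or `"poisson"` (attempts as a seeded Poisson process).
#' @param seed Integer seed for the `"poisson"` mode.
#' @param name Regimen label.
#' @param preop_events List of `bolus_event()`/`infusion_segment()` given
#'   around surgery (typically before t = 0).
#' @param pca A `pca_program()`.
#' @param policy A `demand_policy()`.
#' @param rescue_events List of explicit `bolus_event()`s (e.g. a 25 ug rescue
#'   in the recovery room); pain is not simulated, so rescue times are user
#'   supplied.
#' @return Objects of class `bolus_event`, `infusion_segment`, `pca_program`,
#'   `demand_policy` and `regimen` respectively.
#' @examples
#' regimen(
#'   name = "demand_only",
#'   preop_events = list(bolus_event(-10, 50)),
#'   pca = pca_program(demand_dose = 10, lockout = 10)
#' )
#' @name dosing-events
NULL

#' @rdname dosing-events
#' @export
bolus_event <- function(t, dose) {
  if (!is.numeric(t) || length(t) != 1L || !is.finite(t))
    stop("bolus_event: 't' must be a single finite time", call. = FALSE)
  if (!is.numeric(dose) || length(dose) != 1L || !is.finite(dose) || dose < 0)
    stop("bolus_event: 'dose' must be a single non-negative number", call. = FALSE)
  structure(list(t = as.numeric(t), dose = as.numeric(dose)), class = "bolus_event")
}

#' @rdname dosing-events
#' @export
infusion_segment <- function(t_start, t_end, rate) {
  if (!is.numeric(t_start) || length(t_start) != 1L || !is.finite(t_start))
    stop("infusion_segment: 't_start' must be a single finite time", call. = FALSE)
  if (!is.numeric(t_end) || length(t_end) != 1L || is.na(t_end) || t_end <= t_start)
    stop("infusion_segment: 't_end' must exceed 't_start'", call. = FALSE)
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate < 0)
    stop("infusion_segment: 'rate' must be a single non-negative ug/h value", call. = FALSE)
  structure(list(t_start = as.numeric(t_start), t_end = as.numeric(t_end),
                 rate = as.numeric(rate)), class = "infusion_segment")
}

#' @rdname dosing-events
#' @export
pca_program <- function(demand_dose = 0, lockout = 1, basal = list()) {
  if (!is.numeric(demand_dose) || length(demand_dose) != 1L ||
      !is.finite(demand_dose) || demand_dose < 0)
    stop("pca_program: 'demand_dose' must be a single non-negative dose", call. = FALSE)
  if (!is.numeric(lockout) || length(lockout) != 1L || !is.finite(lockout) || lockout <= 0)
    stop("pca_program: 'lockout' must be a single positive number of minutes", call. = FALSE)
  if (!is.list(basal) || !all(vapply(basal, inherits, TRUE, "infusion_segment")))
    stop("pca_program: 'basal' must be a list of infusion_segment objects", call. = FALSE)
  check_no_overlap(basal, "basal")
  structure(list(demand_dose = as.numeric(demand_dose),
                 lockout = as.numeric(lockout), basal = basal),
            class = "pca_program")
}

#' @rdname dosing-events
#' @export
demand_policy <- function(mode = c("none", "worst_case", "poisson"),
                          rate = NULL, seed = NULL) {
  mode <- match.arg(mode)
  if (mode == "poisson") {
    if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0)
      stop("demand_policy: poisson mode needs 'rate' > 0 attempts/h", call. = FALSE)
    rate <- as.numeric(rate)
    if (is.null(seed) || !is.numeric(seed) || length(seed) != 1L || is.na(seed))
      stop("demand_policy: poisson mode needs an integer 'seed'", call. = FALSE)
    seed <- as.integer(seed)
  } else {
    rate <- NULL
    seed <- NULL
  }
  structure(list(mode = mode, rate = rate, seed = seed), class = "demand_policy")
}

#' @rdname dosing-events
#' @export
regimen <- function(name, preop_events = list(), pca = pca_program(),
                    policy = demand_policy("none"), rescue_events = list()) {
  stopifnot(is.character(name), length(name) == 1L,
            inherits(pca, "pca_program"), inherits(policy, "demand_policy"))
  ok <- vapply(preop_events, function(e)
    inherits(e, "bolus_event") || inherits(e, "infusion_segment"), TRUE)
  if (!all(ok))
    stop("regimen: 'preop_events' must contain bolus_event/infusion_segment objects",
         call. = FALSE)
  if (!all(vapply(rescue_events, inherits, TRUE, "bolus_event")))
    stop("regimen: 'rescue_events' must be bolus_event objects", call. = FALSE)
  check_no_overlap(Filter(function(e) inherits(e, "infusion_segment"), preop_events),
                   "preop infusion")
  structure(list(name = name, preop_events = preop_events, pca = pca,
                 policy = policy, rescue_events = rescue_events),
            class = "regimen")
}

#' @export
print.regimen <- function(x, ...) {
  cat("Regimen:", x$name, "\n")
  for (e in x$preop_events) {
    if (inherits(e, "bolus_event"))
      cat(sprintf("  preop bolus %g ug at t = %g min\n", e$dose, e$t))
    else
      cat(sprintf("  preop infusion %g ug/h on [%g, %g) min\n", e$rate, e$t_start, e$t_end))
  }
  cat(sprintf("  PCA: demand %g ug, lockout %g min, %d basal segment(s)\n",
              x$pca$demand_dose, x$pca$lockout, length(x$pca$basal)))
  for (s in x$pca$basal)
    cat(sprintf("    basal %g ug/h on [%g, %g) min\n", s$rate, s$t_start, s$t_end))
  cat("  demand policy:", x$policy$mode, "\n")
  if (length(x$rescue_events))
    cat("  rescue boluses at t =",
        paste(vapply(x$rescue_events, `[[`, 0, "t"), collapse = ", "), "min\n")
  invisible(x)
}

check_no_overlap <- function(segments, what) {
  if (length(segments) < 2L) return(invisible(TRUE))
  ord <- order(vapply(segments, `[[`, 0, "t_start"))
  segments <- segments[ord]
  for (i in seq_len(length(segments) - 1L)) {
    if (segments[[i]]$t_end > segments[[i + 1L]]$t_start + 1e-9)
      stop(sprintf("overlapping %s segments: [%g, %g) and [%g, %g)", what,
                   segments[[i]]$t_start, segments[[i]]$t_end,
                   segments[[i + 1L]]$t_start, segments[[i + 1L]]$t_end),
           call. = FALSE)
  }
  invisible(TRUE)
}

#' Apply the PCA lockout to a sequence of demand attempts
#'
#' An attempt is granted iff no demand has been granted yet or at least one
#' lockout interval has elapsed since the last *granted* demand. Rejected
#' attempts do not restart the lockout clock.
#'
#' @param pca A [pca_program()].
#' @param attempts Sorted numeric vector of attempt times (minutes).
#' @return A list with `granted` (times of granted demand boluses, each
#'   delivering `demand_dose`) and `log`, a data frame with one row per
#'   attempt (`time`, `granted`, `reason`).
#' @examples
#' g <- grant_demands(pca_program(10, lockout = 10), c(0, 5, 10))
#' g$granted  # 0 and 10; the attempt at 5 falls in the lockout
#' @export
grant_demands <- function(pca, attempts) {
  stopifnot(inherits(pca, "pca_program"))
  attempts <- as.numeric(attempts)
  if (anyNA(attempts) || any(!is.finite(attempts)))
    stop("grant_demands: attempt times must be finite", call. = FALSE)
  if (is.unsorted(attempts))
    stop("grant_demands: attempt times must be sorted increasingly", call. = FALSE)
  n <- length(attempts)
  granted <- logical(n)
  reason <- character(n)
  last <- -Inf
  for (i in seq_len(n)) {
    if (attempts[i] - last >= pca$lockout - 1e-9) {
      granted[i] <- TRUE
      reason[i] <- "granted"
      last <- attempts[i]
    } else {
      reason[i] <- sprintf("lockout until %g", last + pca$lockout)
    }
  }
  list(granted = attempts[granted],
       log = data.frame(time = attempts, granted = granted, reason = reason))
}

#' Generate demand-attempt times from a demand policy
#'
#' `"none"` yields no attempts. `"worst_case"` is the limit of continuous
#' pressing: attempts (all of which are granted) exactly every lockout
#' interval from `t_start`. `"poisson"` draws a homogeneous Poisson process of
#' attempts at the policy's rate, reproducibly from its seed; the caller's RNG
#' state is left untouched.
#'
#' @param policy A [demand_policy()].
#' @param pca The [pca_program()] (supplies the lockout for `"worst_case"`).
#' @param t_start,t_end Attempt window in minutes (PCA is available from the
#'   end of surgery, so `t_start = 0` by default).
#' @return Sorted numeric vector of attempt times.
#' @export
demand_attempts <- function(policy, pca, t_start = 0, t_end) {
  stopifnot(inherits(policy, "demand_policy"), inherits(pca, "pca_program"))
  if (t_end <= t_start) return(numeric(0))
  switch(policy$mode,
    none = numeric(0),
    worst_case = seq(t_start, t_end, by = pca$lockout),
    poisson = {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
              else assign(".Random.seed", old, envir = globalenv()))
      set.seed(policy$seed)
      rate_min <- policy$rate / 60
      # draw gaps until past t_end; expected count = rate * window
      tt <- t_start
      out <- numeric(0)
      repeat {
        tt <- tt + stats::rexp(1L, rate_min)
        if (tt > t_end) break
        out <- c(out, tt)
      }
      out
    })
}

#' Expand a regimen into a flat, time-ordered event schedule
#'
#' Resolves a [regimen()] over a simulation horizon into the primitive events
#' the simulator consumes: instantaneous boluses (preoperative, granted PCA
#' demands, rescue) and total-infusion-rate breakpoints obtained by
#' superposing all infusion segments. Demand attempts come from the regimen's
#' demand policy unless an explicit `attempts` vector is given; the PCA
#' lockout is applied via [grant_demands()]. Simultaneous events are ordered
#' rate-change first, then bolus.
#'
#' @param r A [regimen()].
#' @param horizon End of the schedule in minutes (open-ended infusion
#'   segments are clipped here).
#' @param attempts Optional explicit demand-attempt times overriding the
#'   policy.
#' @param t_start Start of the schedule (default -10 min, ten minutes before
#'   the end of surgery).
#' @return An object of class `event_schedule`: a list with `boluses`
#'   (data frame `time`, `dose`, `origin`), `rate_steps` (data frame `time`,
#'   `rate_ug_min`; each rate applies from its time until the next step),
#'   `scheduled_dose` (total non-demand dose in ug delivered on
#'   `[t_start, horizon]`), `demand_log` and `horizon`.
#'   `as.data.frame()` gives the flat event table.
#' @examples
#' sched <- expand_regimen(scenario_regimen("group_b"), horizon = 60)
#' sched$scheduled_dose  # 50 ug loading + 20 ug/h * 1 h = 70 ug
#' @export
expand_regimen <- function(r, horizon, attempts = NULL, t_start = -10) {
  stopifnot(inherits(r, "regimen"))
  if (!is.numeric(horizon) || length(horizon) != 1L || horizon <= t_start)
    stop("expand_regimen: 'horizon' must exceed 't_start'", call. = FALSE)

  if (is.null(attempts))
    attempts <- demand_attempts(r$policy, r$pca, t_start = max(0, t_start), t_end = horizon)
  attempts <- attempts[attempts >= t_start & attempts <= horizon]
  grants <- grant_demands(r$pca, attempts)

  bol <- data.frame(time = numeric(0), dose = numeric(0), origin = character(0))
  add_bol <- function(df, time, dose, origin) {
    if (length(time) == 0L) return(df)
    rbind(df, data.frame(time = time, dose = dose, origin = origin))
  }
  pre_bol <- Filter(function(e) inherits(e, "bolus_event"), r$preop_events)
  bol <- add_bol(bol, vapply(pre_bol, `[[`, 0, "t"), vapply(pre_bol, `[[`, 0, "dose"),
                 "scheduled")
  bol <- add_bol(bol, grants$granted,
                 rep(r$pca$demand_dose, length(grants$granted)), "demand")
  bol <- add_bol(bol, vapply(r$rescue_events, `[[`, 0, "t"),
                 vapply(r$rescue_events, `[[`, 0, "dose"), "rescue")
  if (nrow(bol) && any(bol$time < t_start))
    stop("expand_regimen: bolus before the simulation start", call. = FALSE)
  if (nrow(bol) && any(bol$time > horizon + 1e-9))
    stop("expand_regimen: bolus after the simulation horizon", call. = FALSE)
  bol <- bol[order(bol$time), , drop = FALSE]
  rownames(bol) <- NULL

  segs <- c(Filter(function(e) inherits(e, "infusion_segment"), r$preop_events),
            r$pca$basal)
  if (length(segs) && any(vapply(segs, `[[`, 0, "t_start") < t_start - 1e-9))
    stop("expand_regimen: infusion segment starts before the simulation start",
         call. = FALSE)
  # superpose segments into a step function of the total rate (ug/min)
  brk <- sort(unique(c(t_start,
                       unlist(lapply(segs, function(s)
                         c(s$t_start, min(s$t_end, horizon)))))))
  brk <- brk[brk >= t_start & brk < horizon]
  rate_at <- function(tt) {
    sum(vapply(segs, function(s)
      if (tt >= s$t_start - 1e-9 && tt < s$t_end - 1e-9) s$rate else 0, 0)) / 60
  }
  rates <- vapply(brk, function(b) rate_at(b + 1e-9), 0)
  keep <- c(TRUE, abs(diff(rates)) > 0)
  rate_steps <- data.frame(time = brk[keep], rate_ug_min = rates[keep])

  sched_bol <- sum(bol$dose[bol$origin != "demand"])
  sched_inf <- sum(vapply(segs, function(s) {
    a <- max(s$t_start, t_start); b <- min(s$t_end, horizon)
    if (b > a) (b - a) * s$rate / 60 else 0
  }, 0))

  structure(list(boluses = bol, rate_steps = rate_steps,
                 scheduled_dose = sched_bol + sched_inf,
                 demand_log = grants$log,
                 t_start = t_start, horizon = horizon),
            class = "event_schedule")
}

#' @export
as.data.frame.event_schedule <- function(x, ...) {
  n_r <- nrow(x$rate_steps)
  n_b <- nrow(x$boluses)
  rates <- data.frame(time = x$rate_steps$time,
                      type = rep("rate_change", n_r),
                      dose_ug = rep(NA_real_, n_r),
                      rate_ug_min = x$rate_steps$rate_ug_min,
                      origin = rep("scheduled", n_r))
  bol <- data.frame(time = x$boluses$time, type = rep("bolus", n_b),
                    dose_ug = x$boluses$dose, rate_ug_min = rep(NA_real_, n_b),
                    origin = x$boluses$origin)
  out <- rbind(rates, bol)
  # tie-break at equal times: rate change applies before the bolus
  out <- out[order(out$time, match(out$type, c("rate_change", "bolus"))), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.event_schedule <- function(x, ...) {
  cat(sprintf("Event schedule on [%g, %g] min: %d bolus(es), %d rate step(s), scheduled dose %g ug\n",
              x$t_start, x$horizon, nrow(x$boluses), nrow(x$rate_steps),
              x$scheduled_dose))
  print(utils::head(as.data.frame(x), 12))
  invisible(x)
}
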