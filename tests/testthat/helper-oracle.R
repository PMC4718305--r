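# Independent numerical oracle: adaptive ODE integration (deSolve::lsoda) of
# the three-compartment + effect-site system, written directly from the model
# equations and fed with plain event tables, so it shares no code with the
# package's matrix-exponential propagator.

oracle_deriv <- function(t, y, p, rate) {
  list(c(
    -(p$k10 + p$k12 + p$k13) * y[1] + p$k21 * y[2] + p$k31 * y[3] + rate,
    p$k12 * y[1] - p$k21 * y[2],
    p$k13 * y[1] - p$k31 * y[3],
    p$ke0 * (y[1] / p$v_central - y[4])
  ))
}

# boluses: data.frame(time, dose); rate_steps: data.frame(time, rate_ug_min),
# each rate applying from its time to the next step. Integrates piecewise so
# every discontinuity is a segment boundary; returns states at `times`.
ode_oracle <- function(params, times, boluses = NULL, rate_steps = NULL,
                       rtol = 1e-11, atol = 1e-13) {
  if (is.null(boluses)) boluses <- data.frame(time = numeric(0), dose = numeric(0))
  if (is.null(rate_steps)) rate_steps <- data.frame(time = numeric(0),
                                                    rate_ug_min = numeric(0))
  brk <- sort(unique(c(times, boluses$time, rate_steps$time)))
  y <- c(0, 0, 0, 0)
  out <- matrix(NA_real_, length(times), 4)
  record <- function(tt, y) {
    hit <- which(abs(times - tt) < 1e-9)
    if (length(hit)) out[hit, ] <<- rep(y, each = length(hit))
  }
  for (k in seq_along(brk)) {
    tk <- brk[k]
    if (k > 1L && tk > brk[k - 1L]) {
      i <- findInterval(brk[k - 1L] + 1e-12, rate_steps$time)
      rate <- if (i == 0) 0 else rate_steps$rate_ug_min[i]
      sol <- deSolve::lsoda(y, c(brk[k - 1L], tk), oracle_deriv, params,
                            rate = rate, rtol = rtol, atol = atol)
      y <- as.numeric(sol[nrow(sol), -1])
    }
    ib <- which(abs(boluses$time - tk) < 1e-9)
    if (length(ib)) y[1] <- y[1] + sum(boluses$dose[ib])
    record(tk, y)
  }
  colnames(out) <- c("a1", "a2", "a3", "ce")
  out
}

# independent brute-force reference for the pump lockout rule
brute_force_grants <- function(attempts, lockout) {
  granted <- numeric(0)
  for (a in attempts) {
    if (length(granted) == 0 || a - granted[length(granted)] >= lockout - 1e-9)
      granted <- c(granted, a)
  }
  granted
}

# random but physiologic-ish parameter draws for property tests
random_params <- function() {
  pk_parameters(
    v_central = runif(1, 5, 60),
    k10 = runif(1, 0.005, 0.1),
    k12 = runif(1, 0.01, 0.3),
    k13 = runif(1, 0.005, 0.2),
    k21 = runif(1, 0.01, 0.2),
    k31 = runif(1, 0.005, 0.05),
    ke0 = runif(1, 0.05, 0.5)
  )
}

# small random regimen (boluses + one or two infusion segments) on [0, 120]
random_regimen <- function(name = "rand") {
  n_bol <- sample(0:3, 1)
  boluses <- lapply(seq_len(n_bol), function(i)
    bolus_event(round(runif(1, 0, 90), 2), round(runif(1, 5, 60), 1)))
  n_seg <- sample(0:2, 1)
  segs <- list()
  t0 <- 0
  for (i in seq_len(n_seg)) {
    t1 <- t0 + round(runif(1, 5, 40), 2)
    segs <- c(segs, list(infusion_segment(t0, t1, round(runif(1, 0, 60), 1))))
    t0 <- t1 + round(runif(1, 0, 10), 2)
  }
  regimen(name, preop_events = c(boluses, segs))
}

# event tables of a simulated series, in the oracle's input format
series_event_tables <- function(ser) {
  list(boluses = ser$events$boluses[, c("time", "dose")],
       rate_steps = ser$events$rate_steps)
}
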