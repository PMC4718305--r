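#' System state of the compartmental model
#'
#' A snapshot of the model at one time point: amounts (ug) in the central,
#' fast-peripheral and slow-peripheral compartments, and the effect-site
#' concentration (ng/mL). Time is in minutes, with 0 conventionally the end
#' of surgery.
#'
#' @param t Time in minutes.
#' @param a1,a2,a3 Compartment amounts in micrograms (central, fast
#'   peripheral, slow peripheral).
#' @param ce Effect-site concentration in ng/mL.
#' @return An object of class `system_state`.
#' @examples
#' system_state()                       # everything zero at t = 0
#' apply_bolus(system_state(t = -10), 50)
#' @export
system_state <- function(t = 0, a1 = 0, a2 = 0, a3 = 0, ce = 0) {
  vals <- c(t = t, a1 = a1, a2 = a2, a3 = a3, ce = ce)
  if (!all(is.finite(vals))) stop("system_state: all fields must be finite", call. = FALSE)
  if (any(vals[c("a1", "a2", "a3", "ce")] < 0))
    stop("system_state: amounts and concentrations must be non-negative", call. = FALSE)
  structure(list(t = t, a1 = a1, a2 = a2, a3 = a3, ce = ce),
            class = "system_state")
}

#' @export
print.system_state <- function(x, ...) {
  cat(sprintf("state @ t = %g min: a = (%g, %g, %g) ug, ce = %g ng/mL\n",
              x$t, x$a1, x$a2, x$a3, x$ce))
  invisible(x)
}

#' Plasma concentration of a state
#'
#' @param state A [system_state()].
#' @param params A [pk_parameters()] (supplies the central volume).
#' @return Plasma concentration in ng/mL (`a1 / v_central`).
#' @export
plasma_conc <- function(state, params) state$a1 / params$v_central

#' Rate matrix of the linear dosing system
#'
#' The 4x4 coefficient matrix A of dx/dt = A x (+ infusion forcing into the
#' central compartment), with state ordering (a1, a2, a3, ce):
#' da1/dt = -(k10+k12+k13) a1 + k21 a2 + k31 a3,
#' da2/dt = k12 a1 - k21 a2, da3/dt = k13 a1 - k31 a3,
#' dce/dt = ke0 (a1/v_central - ce).
#' The 3x3 amount block conserves mass up to elimination: its column sums are
#' (-k10, 0, 0).
#'
#' @param params A [pk_parameters()].
#' @return A 4x4 numeric matrix (units 1/min) with dimnames
#'   `c("a1","a2","a3","ce")`.
#' @examples
#' A <- rate_matrix(pk_parameters())
#' A["a1", "a1"]  # -(k10 + k12 + k13)
#' @export
rate_matrix <- function(params) {
  stopifnot(inherits(params, "pk_parameters"))
  with(params, {
    A <- matrix(c(
      -(k10 + k12 + k13), k21,  k31,  0,
      k12,               -k21,  0,    0,
      k13,                0,   -k31,  0,
      ke0 / v_central,    0,    0,   -ke0
    ), nrow = 4, byrow = TRUE,
    dimnames = list(c("a1", "a2", "a3", "ce"), c("a1", "a2", "a3", "ce")))
    A
  })
}

# Transition matrix of the augmented homogeneous system over a step dt.
# The zero-order infusion is absorbed into a fifth, constant state u
# (d u/dt = 0, da1/dt += u), so Phi = expm([A e1; 0 0] * dt) propagates any
# (state, rate) pair exactly and is independent of the rate itself.
transition_matrix <- function(params, dt) {
  A <- rate_matrix(params)
  aug <- rbind(cbind(A, c(1, 0, 0, 0)), rep(0, 5))
  as.matrix(Matrix::expm(Matrix::Matrix(aug * dt)))
}

# Memoising wrapper: simulations take many steps with only a handful of
# distinct dt values, so one expm per distinct dt suffices.
make_propagator <- function(params) {
  cache <- new.env(parent = emptyenv())
  function(dt) {
    key <- sprintf("%.17g", dt)
    Phi <- cache[[key]]
    if (is.null(Phi)) {
      Phi <- transition_matrix(params, dt)
      cache[[key]] <- Phi
    }
    Phi
  }
}

# Core step on a bare numeric state vector c(a1, a2, a3, ce); used by the
# simulation loop where system_state boxing would dominate runtime.
step_vector <- function(x, Phi, rate_ug_min) {
  y <- Phi %*% c(x, rate_ug_min)
  y <- y[1:4]
  # expm of a Metzler matrix is non-negative; clamp roundoff-level dust only
  y[y < 0 & y > -1e-9] <- 0
  y
}

#' Propagate the system exactly over a constant-rate interval
#'
#' Advances a [system_state()] by `dt` minutes under a constant zero-order
#' infusion into the central compartment, using the matrix exponential of the
#' augmented linear system. This is the exact solution of the inhomogeneous
#' ODE, not a numerical integration: results are independent of how an
#' interval is subdivided.
#'
#' @param state A [system_state()].
#' @param params A [pk_parameters()].
#' @param infusion_rate Zero-order infusion rate in ug/min (constant over the
#'   interval). Default 0.
#' @param dt Interval length in minutes (`dt = 0` returns the input state).
#' @return The [system_state()] at `t + dt`.
#' @examples
#' s <- apply_bolus(system_state(), 50)
#' propagate(s, pk_parameters(), dt = 30)
#' @export
propagate <- function(state, params, infusion_rate = 0, dt) {
  stopifnot(inherits(state, "system_state"), inherits(params, "pk_parameters"))
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt < 0)
    stop("propagate: 'dt' must be a single non-negative number", call. = FALSE)
  if (!is.numeric(infusion_rate) || length(infusion_rate) != 1L ||
      !is.finite(infusion_rate) || infusion_rate < 0)
    stop("propagate: 'infusion_rate' must be a single non-negative number", call. = FALSE)
  if (dt == 0) return(state)
  y <- step_vector(c(state$a1, state$a2, state$a3, state$ce),
                   transition_matrix(params, dt), infusion_rate)
  system_state(t = state$t + dt, a1 = y[1], a2 = y[2], a3 = y[3], ce = y[4])
}

#' Apply an instantaneous intravenous bolus
#'
#' Adds `dose` micrograms to the central compartment; peripheral amounts, the
#' effect-site concentration and time are unchanged. Plasma concentration
#' therefore jumps by `dose / v_central`.
#'
#' @param state A [system_state()].
#' @param dose Bolus dose in micrograms (>= 0).
#' @return The updated [system_state()].
#' @export
apply_bolus <- function(state, dose) {
  stopifnot(inherits(state, "system_state"))
  if (!is.numeric(dose) || length(dose) != 1L || !is.finite(dose) || dose < 0)
    stop("apply_bolus: 'dose' must be a single non-negative number", call. = FALSE)
  state$a1 <- state$a1 + dose
  state
}
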