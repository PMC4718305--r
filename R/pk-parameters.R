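#' Pharmacokinetic parameters for the three-compartment fentanyl model
#'
#' Builds the parameter set of a linear mammillary three-compartment model
#' with an additional first-order effect-site compartment. The defaults are
#' the fentanyl point estimates used throughout the package: central volume
#' 26.6 L and micro rate constants (per minute) k10 = 0.0332, k12 = 0.172,
#' k13 = 0.131, k21 = 0.1, k31 = 0.0177, with effect-site equilibration
#' ke0 = 0.147. Amounts are carried in micrograms, volumes in litres and time
#' in minutes, so plasma concentration `a1 / v_central` is in ug/L, which is
#' numerically identical to ng/mL.
#'
#' @param v_central Central (plasma) distribution volume in litres.
#' @param k10 Elimination rate constant from the central compartment (1/min).
#' @param k12,k21 Transfer rate constants central <-> fast peripheral (1/min).
#' @param k13,k31 Transfer rate constants central <-> slow peripheral (1/min).
#' @param ke0 First-order plasma/effect-site equilibration rate constant
#'   (1/min). The effect compartment carries a concentration, not an amount,
#'   so no effect-site volume is needed.
#'
#' @return An object of class `pk_parameters`.
#' @examples
#' pk_parameters()
#' @export
pk_parameters <- function(v_central = 26.6,
                          k10 = 0.0332, k12 = 0.172, k13 = 0.131,
                          k21 = 0.1, k31 = 0.0177, ke0 = 0.147) {
  p <- list(v_central = v_central, k10 = k10, k12 = k12, k13 = k13,
            k21 = k21, k31 = k31, ke0 = ke0)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("pk_parameters: '", nm, "' must be a single strictly positive number",
           call. = FALSE)
    }
  }
  structure(p, class = "pk_parameters")
}

#' @export
print.pk_parameters <- function(x, ...) {
  cat("Three-compartment + effect-site PK parameters\n")
  cat(sprintf("  v_central: %g L\n", x$v_central))
  cat(sprintf("  k10 %g, k12 %g, k13 %g, k21 %g, k31 %g (1/min)\n",
              x$k10, x$k12, x$k13, x$k21, x$k31))
  cat(sprintf("  ke0: %g 1/min\n", x$ke0))
  invisible(x)
}

#' Therapeutic concentration window
#'
#' Defines the analgesic window against which simulated concentrations are
#' judged: a lower bound at the minimal effective concentration (MEC, default
#' 0.23 ng/mL for fentanyl) and an upper bound above which side effects become
#' a concern (default 2 ng/mL). `reference` selects which concentration is
#' evaluated; the effect-site concentration is the default because it drives
#' analgesia with the equilibration lag.
#'
#' @param mec Lower bound (ng/mL), the minimal effective concentration.
#' @param upper Upper bound (ng/mL).
#' @param reference `"effect_site"` or `"plasma"`.
#' @return An object of class `therapeutic_window`.
#' @examples
#' therapeutic_window()
#' therapeutic_window(reference = "plasma")
#' @export
therapeutic_window <- function(mec = 0.23, upper = 2.0,
                               reference = c("effect_site", "plasma")) {
  reference <- match.arg(reference)
  if (!is.numeric(mec) || length(mec) != 1L || !is.finite(mec) || mec <= 0)
    stop("therapeutic_window: 'mec' must be a single positive number", call. = FALSE)
  if (!is.numeric(upper) || length(upper) != 1L || !is.finite(upper) || upper <= mec)
    stop("therapeutic_window: 'upper' must exceed 'mec'", call. = FALSE)
  structure(list(mec = mec, upper = upper, reference = reference),
            class = "therapeutic_window")
}

#' @export
print.therapeutic_window <- function(x, ...) {
  cat(sprintf("Therapeutic window: [%g, %g] ng/mL on the %s concentration\n",
              x$mec, x$upper, gsub("_", "-", x$reference)))
  invisible(x)
}
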