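#' Time-varying elastance chamber parameters
#'
#' A contractile chamber (atrium, whole ventricle, or ventricular compartment)
#' is described by a maximal elastance `Emax` (slope of the end-systolic
#' pressure-volume relation), a time to peak elastance `Tmax`, the exponential
#' end-diastolic pressure-volume relation (EDPVR) constants `A` and `B`, and an
#' unstressed volume `V0`.
#'
#' @param Emax Maximal elastance (mmHg/ml).
#' @param Tmax Time to maximal elastance (ms).
#' @param A EDPVR scaling factor (mmHg).
#' @param B EDPVR exponent (1/ml).
#' @param V0 Unstressed volume (ml).
#'
#' @return An object of class `chamber_params`.
#' @examples
#' ventricle_unit_params()
#' compartment_parameters(1.0) # the assembled total ventricle
#' @export
chamber_params <- function(Emax, Tmax, A, B, V0) {
  vals <- c(Emax = Emax, Tmax = Tmax, A = A, B = B, V0 = V0)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all chamber parameters (Emax, Tmax, A, B, V0) must be finite and > 0")
  }
  structure(as.list(vals), class = "chamber_params")
}

#' @export
print.chamber_params <- function(x, ...) {
  cat("<chamber_params>  Emax", x$Emax, "mmHg/ml  Tmax", x$Tmax, "ms  A",
      x$A, "mmHg  B", signif(x$B, 5), "/ml  V0", x$V0, "ml\n")
  invisible(x)
}

#' Default atrial chamber parameters
#' @return A [chamber_params()] object for the single atrium.
#' @export
atrium_params <- function() {
  chamber_params(Emax = 1.00, Tmax = 120, A = 0.80, B = 0.08, V0 = 10.0)
}

#' Default per-unit ventricular parameters
#'
#' The ventricle is modelled as 20 identical contractile units (one unit = 5%
#' of the total ventricle); compartments of any size are assembled from units
#' with [compartment_parameters()].
#' @return A [chamber_params()] object for one ventricular unit.
#' @export
ventricle_unit_params <- function() {
  chamber_params(Emax = 62.0, Tmax = 290, A = 0.28, B = 0.80, V0 = 0.77)
}

#' Normalized activation waveform
#'
#' Raised-cosine activation: rises from 0 at the activation onset to 1 at
#' `Tmax`, relaxes back to 0 over a window of `Tmax/2`, and stays 0 for the
#' rest of the cycle. Drives the interpolation between the passive (EDPVR) and
#' active (ESPVR) chamber laws.
#'
#' @param t_since_onset Time since the chamber's activation onset (ms); may be
#'   a vector. Values are not wrapped: callers handle cycle phase.
#' @param Tmax Time to peak activation (ms).
#' @param relax_fraction Relaxation window length as a fraction of `Tmax`
#'   (default 0.5, i.e. total active duration `1.5 * Tmax`).
#' @return Activation fraction in `[0, 1]`, same length as `t_since_onset`.
#' @examples
#' activation_fraction(c(0, 290, 362.5, 500), 290)
#' @export
activation_fraction <- function(t_since_onset, Tmax, relax_fraction = 0.5) {
  if (!is.finite(Tmax) || Tmax <= 0) stop("Tmax must be finite and > 0")
  if (relax_fraction <= 0) stop("relax_fraction must be > 0")
  t <- t_since_onset
  e <- numeric(length(t))
  rise <- t >= 0 & t < Tmax
  fall <- t >= Tmax & t < (1 + relax_fraction) * Tmax
  e[rise] <- 0.5 * (1 - cos(pi * t[rise] / Tmax))
  e[fall] <- 0.5 * (1 + cos(pi * (t[fall] - Tmax) / (relax_fraction * Tmax)))
  # exact endpoints (guard against cos() rounding)
  e[t == Tmax] <- 1
  e
}

#' Passive (end-diastolic) chamber pressure
#'
#' Exponential EDPVR `P = A * (exp(B * (V - V0)) - 1)`. Zero at `V = V0`;
#' negative distension (`V < V0`) yields a negative pressure, which small
#' compartments can reach under paradoxical stretch.
#'
#' @param V Chamber volume (ml); may be a vector.
#' @param params A [chamber_params()] object.
#' @return Pressure (mmHg).
#' @export
end_diastolic_pressure <- function(V, params) {
  params$A * (exp(params$B * (V - params$V0)) - 1)
}

#' Active (end-systolic) chamber pressure
#'
#' Linear ESPVR `P = Emax * (V - V0)`.
#'
#' @inheritParams end_diastolic_pressure
#' @return Pressure (mmHg).
#' @export
end_systolic_pressure <- function(V, params) {
  params$Emax * (V - params$V0)
}

#' Instantaneous chamber pressure
#'
#' Time-varying elastance law: the activation fraction `e(t)` interpolates
#' between the passive EDPVR and the active ESPVR,
#' `P = Ped(V) + e(t) * (Pes(V) - Ped(V))`.
#'
#' @inheritParams end_diastolic_pressure
#' @param t_since_onset Time since activation onset (ms).
#' @param relax_fraction Passed to [activation_fraction()].
#' @return Pressure (mmHg).
#' @export
instantaneous_pressure <- function(V, t_since_onset, params,
                                   relax_fraction = 0.5) {
  e <- activation_fraction(t_since_onset, params$Tmax, relax_fraction)
  ped <- end_diastolic_pressure(V, params)
  ped + e * (end_systolic_pressure(V, params) - ped)
}

#' Assemble a ventricular compartment from identical units
#'
#' A compartment holding a fraction `f` of the total ventricle consists of
#' `n = 20 * f` units in parallel. Parallel composition scales the per-unit
#' constants as `Emax -> Emax/n`, `B -> B/n`, `V0 -> n * V0`, with `A` and
#' `Tmax` unchanged, so that compartments at a common pressure always hold the
#' same total volume as the single assembled chamber.
#'
#' @param fraction Fraction of the total ventricle in `(0, 1]`. Must be a
#'   multiple of 0.05 (a whole number of units) unless `continuous = TRUE`.
#' @param unit Per-unit parameters, default [ventricle_unit_params()].
#' @param n_units Number of units making up the whole ventricle (default 20).
#' @param continuous Allow non-integer numbers of units.
#' @return A [chamber_params()] object for the compartment.
#' @examples
#' compartment_parameters(0.70) # n = 14 units
#' @export
compartment_parameters <- function(fraction, unit = ventricle_unit_params(),
                                   n_units = 20, continuous = FALSE) {
  if (!is.finite(fraction) || fraction <= 0 || fraction > 1) {
    stop("fraction must lie in (0, 1]")
  }
  n <- n_units * fraction
  if (!continuous && abs(n - round(n)) > 1e-8) {
    stop("fraction must be a multiple of ", format(1 / n_units),
         " (whole units); use continuous = TRUE to override")
  }
  chamber_params(Emax = unit$Emax / n, Tmax = unit$Tmax, A = unit$A,
                 B = unit$B / n, V0 = unit$V0 * n)
}

#' Passive chamber volume at a given pressure (inverse EDPVR)
#'
#' @param P Pressure (mmHg), `P > -A`.
#' @param params A [chamber_params()] object.
#' @return Volume (ml).
#' @keywords internal
edpvr_volume <- function(P, params) {
  params$V0 + log(P / params$A + 1) / params$B
}
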