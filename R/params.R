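#' Circulation model parameters
#'
#' Builds the full parameter set of the closed-loop Fontan (total
#' cavopulmonary connection) circulation: a two-compartment ventricle and a
#' single atrium (time-varying elastance chambers), systemic and pulmonary
#' three-element Windkessel beds connected in series, a Bernoulli
#' atrioventricular valve with inertance, an aortic valve modelled as an ideal
#' diode with a small series resistance, and an intercompartment
#' (intraventricular) communication resistance. Defaults reproduce typical
#' postoperative hemodynamics of a 40-kg Fontan patient.
#'
#' @param HR Heart rate (beats/min).
#' @param PR Atrioventricular (PR) interval (ms): delay from atrial to
#'   ventricular activation onset.
#' @param total_stressed_volume Total stressed blood volume (ml): sum of all
#'   compliance stressed volumes plus chamber volumes above their unstressed
#'   volumes; conserved by the dynamics.
#' @param BSA Body surface area (m^2), used only for indexing.
#' @param systemic,pulmonary Named lists with characteristic impedance
#'   `Z_art` (mmHg s/ml), arterial compliance `C_art` (ml/mmHg), arterial
#'   resistance `R_art` (mmHg s/ml), venous compliance `C_ven` (ml/mmHg) and
#'   venous resistance `R_ven` (mmHg s/ml).
#' @param av_valve Named list: effective orifice area `EOA` (cm^2), inertance
#'   `L` (mmHg s^2/ml), blood density `rho` (g/ml) and the Bernoulli constant
#'   `K` (g s^-2 cm^-1 mmHg^-1).
#' @param aortic_valve_R Aortic valve series resistance (mmHg s/ml).
#' @param intercompartment_R Resistance of the communication between the two
#'   ventricular compartments (mmHg s/ml).
#' @param atrium,ventricle_unit [chamber_params()] for the atrium and for one
#'   ventricular unit (1/20 of the ventricle).
#' @param delayed_fraction Fraction of the total ventricle activated late, in
#'   `(0, 1)`; multiples of 0.05 by default (see [compartment_parameters()]).
#' @param delay_dT Activation delay of the delayed compartment (ms, >= 0).
#'
#' @return An object of class `fontan_params`.
#' @examples
#' p <- fontan_params(delayed_fraction = 0.7, delay_dT = 60)
#' @export
fontan_params <- function(HR = 80,
                          PR = 100,
                          total_stressed_volume = 720,
                          BSA = 1.35,
                          systemic = list(Z_art = 0.04, C_art = 1.10,
                                          R_art = 1.05, C_ven = 35.0,
                                          R_ven = 0.050),
                          pulmonary = list(Z_art = 0.01, C_art = 2.5,
                                           R_art = 0.040, C_ven = 3.0,
                                           R_ven = 0.010),
                          av_valve = list(EOA = 5.0, L = 0.0003,
                                          rho = 1.06, K = 1333),
                          aortic_valve_R = 0.005,
                          intercompartment_R = 0.008,
                          atrium = atrium_params(),
                          ventricle_unit = ventricle_unit_params(),
                          delayed_fraction = 0.70,
                          delay_dT = 0) {
  p <- structure(list(HR = HR, PR = PR,
                      total_stressed_volume = total_stressed_volume,
                      BSA = BSA, systemic = systemic, pulmonary = pulmonary,
                      av_valve = av_valve, aortic_valve_R = aortic_valve_R,
                      intercompartment_R = intercompartment_R,
                      atrium = atrium, ventricle_unit = ventricle_unit,
                      delayed_fraction = delayed_fraction,
                      delay_dT = delay_dT),
                 class = "fontan_params")
  validate_fontan_params(p)
  p
}

validate_fontan_params <- function(p) {
  pos <- c(HR = p$HR, PR = p$PR,
           total_stressed_volume = p$total_stressed_volume, BSA = p$BSA,
           unlist(p$systemic), unlist(p$pulmonary), unlist(p$av_valve),
           aortic_valve_R = p$aortic_valve_R,
           intercompartment_R = p$intercompartment_R)
  if (any(!is.finite(pos)) || any(pos <= 0)) {
    bad <- names(pos)[!is.finite(pos) | pos <= 0]
    stop("parameters must be finite and > 0: ", paste(bad, collapse = ", "))
  }
  need <- c("Z_art", "C_art", "R_art", "C_ven", "R_ven")
  for (side in c("systemic", "pulmonary")) {
    if (!all(need %in% names(p[[side]]))) {
      stop(side, " must contain ", paste(need, collapse = ", "))
    }
  }
  if (!all(c("EOA", "L", "rho", "K") %in% names(p$av_valve))) {
    stop("av_valve must contain EOA, L, rho, K")
  }
  if (!inherits(p$atrium, "chamber_params") ||
      !inherits(p$ventricle_unit, "chamber_params")) {
    stop("atrium and ventricle_unit must be chamber_params objects")
  }
  if (!is.finite(p$delayed_fraction) || p$delayed_fraction <= 0 ||
      p$delayed_fraction >= 1) {
    stop("delayed_fraction must lie in (0, 1)")
  }
  if (!is.finite(p$delay_dT) || p$delay_dT < 0) {
    stop("delay_dT must be >= 0 ms")
  }
  invisible(p)
}

#' @export
print.fontan_params <- function(x, ...) {
  cat("<fontan_params>\n")
  cat("  HR", x$HR, "bpm, PR", x$PR, "ms, stressed volume",
      x$total_stressed_volume, "ml, BSA", x$BSA, "m^2\n")
  cat("  delayed fraction", x$delayed_fraction, ", activation delay",
      x$delay_dT, "ms\n")
  invisible(x)
}

#' Read / write a model configuration file
#'
#' The YAML configuration mirrors the parameter-table naming of the model
#' (`E_max`, `T_max`, `A`, `B`, `V_0` for chambers; `Z`, `C`, `R` for the
#' vascular beds), so a configuration can be audited against the published
#' parameter table directly.
#'
#' @param path File path.
#' @param params A [fontan_params()] object (for writing).
#' @return [read_fontan_config()] returns a [fontan_params()] object;
#'   [write_fontan_config()] returns `path` invisibly.
#' @export
read_fontan_config <- function(path) {
  y <- yaml::read_yaml(path)
  cham <- function(z) chamber_params(Emax = z$E_max, Tmax = z$T_max,
                                     A = z$A, B = z$B, V0 = z$V_0)
  bed <- function(z) list(Z_art = z$Z, C_art = z$C_art, R_art = z$R_art,
                          C_ven = z$C_ven, R_ven = z$R_ven)
  fontan_params(
    HR = y$HR, PR = y$PR,
    total_stressed_volume = y$total_stressed_volume,
    BSA = if (is.null(y$BSA)) 1.35 else y$BSA,
    systemic = bed(y$systemic), pulmonary = bed(y$pulmonary),
    av_valve = list(EOA = y$av_valve$EOA, L = y$av_valve$L,
                    rho = y$av_valve$rho, K = y$av_valve$K),
    aortic_valve_R = y$aortic_valve$R,
    intercompartment_R = y$intercompartment$R,
    atrium = cham(y$atrium), ventricle_unit = cham(y$ventricle_unit),
    delayed_fraction = if (is.null(y$delayed_fraction)) 0.70
                       else y$delayed_fraction,
    delay_dT = if (is.null(y$delay_dT)) 0 else y$delay_dT)
}

#' @rdname read_fontan_config
#' @export
write_fontan_config <- function(params, path) {
  validate_fontan_params(params)
  cham <- function(c) list(E_max = c$Emax, T_max = c$Tmax, A = c$A, B = c$B,
                           V_0 = c$V0)
  bed <- function(b) list(Z = b$Z_art, C_art = b$C_art, R_art = b$R_art,
                          C_ven = b$C_ven, R_ven = b$R_ven)
  y <- list(HR = params$HR, PR = params$PR,
            total_stressed_volume = params$total_stressed_volume,
            BSA = params$BSA,
            systemic = bed(params$systemic),
            pulmonary = bed(params$pulmonary),
            av_valve = params$av_valve,
            aortic_valve = list(R = params$aortic_valve_R),
            intercompartment = list(R = params$intercompartment_R),
            atrium = cham(params$atrium),
            ventricle_unit = cham(params$ventricle_unit),
            delayed_fraction = params$delayed_fraction,
            delay_dT = params$delay_dT)
  yaml::write_yaml(y, path)
  invisible(path)
}
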