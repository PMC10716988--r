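#' Pressure drop across the atrioventricular valve
#'
#' Bernoulli orifice law `dP = rho * Q^2 / (2 * K * EOA^2)`: quadratic in flow
#' and zero at zero flow. The valve itself is a diode; callers pass forward
#' flow only.
#'
#' @param Q Forward flow (ml/s, >= 0); may be a vector.
#' @param EOA Effective orifice area (cm^2).
#' @param rho Blood density (g/ml).
#' @param K Unit-conversion constant (g s^-2 cm^-1 mmHg^-1).
#' @return Pressure drop (mmHg).
#' @examples
#' av_valve_pressure_drop(300, EOA = 5, rho = 1.06, K = 1333)
#' @export
av_valve_pressure_drop <- function(Q, EOA = 5.0, rho = 1.06, K = 1333) {
  if (any(Q < 0)) stop("Q must be >= 0 (the valve is a diode)")
  if (EOA <= 0 || rho <= 0 || K <= 0) stop("EOA, rho and K must be > 0")
  rho * Q^2 / (2 * K * EOA^2)
}

# Flatten a fontan_params object into the seconds-based list consumed by the
# compiled integrator. Single conversion layer ms -> s.
flatten_params <- function(params, delayed_fraction = params$delayed_fraction,
                           delay_dT = params$delay_dT) {
  f_d <- delayed_fraction
  f_e <- 1 - f_d
  ve <- compartment_parameters(f_e, unit = params$ventricle_unit,
                               continuous = TRUE)
  vd <- compartment_parameters(f_d, unit = params$ventricle_unit,
                               continuous = TRUE)
  cham_vec <- function(c, ms2s = TRUE) {
    c(Emax = c$Emax, Tmax = if (ms2s) c$Tmax / 1000 else c$Tmax,
      A = c$A, B = c$B, V0 = c$V0)
  }
  list(T = 60 / params$HR,
       onset_a = 0,
       onset_e = params$PR / 1000,
       onset_d = (params$PR + delay_dT) / 1000,
       atr = cham_vec(params$atrium), ve = cham_vec(ve), vd = cham_vec(vd),
       Z_sa = params$systemic$Z_art, C_sa = params$systemic$C_art,
       R_sa = params$systemic$R_art, C_sv = params$systemic$C_ven,
       R_sv = params$systemic$R_ven,
       Z_pa = params$pulmonary$Z_art, C_pa = params$pulmonary$C_art,
       R_pa = params$pulmonary$R_art, C_pv = params$pulmonary$C_ven,
       R_pv = params$pulmonary$R_ven,
       EOA = params$av_valve$EOA, L_av = params$av_valve$L,
       rho = params$av_valve$rho, K_av = params$av_valve$K,
       R_ao = params$aortic_valve_R, R_ic = params$intercompartment_R)
}

# Documented initial volume allocation: ventricle 100 ml split by fraction,
# atrium 30 ml; the remaining stressed volume is distributed over the four
# vascular compliances at a common pressure.
initial_state <- function(params, delayed_fraction = params$delayed_fraction) {
  f_d <- delayed_fraction
  V_vent <- 100
  V_atr <- 30
  V0_vent <- params$ventricle_unit$V0 * 20
  vasc <- params$total_stressed_volume -
    (V_vent - V0_vent) - (V_atr - params$atrium$V0)
  C <- c(params$systemic$C_art, params$systemic$C_ven,
         params$pulmonary$C_art, params$pulmonary$C_ven)
  if (vasc <= 0) stop("total_stressed_volume too small for the initial chamber volumes")
  P0 <- vasc / sum(C)
  c(V_e = (1 - f_d) * V_vent, V_d = f_d * V_vent, V_a = V_atr,
    V_sa = C[1] * P0, V_sv = C[2] * P0, V_pa = C[3] * P0, V_pv = C[4] * P0,
    Q_av = 0)
}

#' Evaluate the circuit's rates of change at one state
#'
#' Exposes the right-hand side of the closed-loop model for inspection and
#' verification: node pressures follow from the compliances (`P = V/C`) and
#' chamber laws, inter-node flows from Ohmic and valve laws, and each stored
#' volume changes as inflow minus outflow, so the volume derivatives always
#' sum to zero.
#'
#' @param state Named numeric vector of length 8: `V_e`, `V_d`, `V_a`, `V_sa`,
#'   `V_sv`, `V_pa`, `V_pv` (ml; chamber volumes absolute, compliance volumes
#'   stressed) and `Q_av` (ml/s).
#' @param t_ms Time (ms) within the cycle; 0 is the atrial activation onset.
#' @param params A [fontan_params()] object.
#' @param av_open Is the atrioventricular valve open?
#' @return A list with `dstate` (per-second rates), `pressures`, `flows` and
#'   `activation`.
#' @export
circuit_derivatives <- function(state, t_ms, params, av_open = TRUE) {
  if (any(!is.finite(state))) stop("non-finite state")
  circuit_derivs_cpp(as.numeric(state), t_ms / 1000, flatten_params(params),
                     av_open)
}

#' Simulate the circulation to periodic steady state
#'
#' Integrates the closed loop from a documented initial volume allocation with
#' a fixed-step fourth-order scheme until beat-to-beat convergence: after a
#' burn-in of `min_beats - 1` beats, successive-beat end-diastolic volume and
#' forward stroke output must both change by less than `tol` (relative). The
#' converged final beat is returned on a uniform output grid together with
#' cardiac event times.
#'
#' @param params A [fontan_params()] object.
#' @param delayed_fraction,delay_dT Optional overrides of the corresponding
#'   `params` fields.
#' @param dt_ms Integration step (ms, <= 0.1 recommended).
#' @param out_dt_ms Output sampling interval (ms); must be a multiple of
#'   `dt_ms` dividing the cycle length.
#' @param min_beats Minimum number of beats before convergence may be declared.
#' @param max_beats Beat cap; exceeding it raises an error (or a warning with
#'   `on_nonconvergence = "warn"`) carrying the last-beat drift.
#' @param tol Relative beat-to-beat drift tolerance.
#' @param on_nonconvergence `"error"` or `"warn"`.
#' @return An object of class `fontan_beat`: list with `traces` (data frame:
#'   time, volumes, pressures, flows, activations over one beat), `events`
#'   (activation onsets and valve open/close times, ms), `convergence`
#'   diagnostics, and the effective `delayed_fraction`, `delay_dT`, `params`.
#' @examples
#' \donttest{
#' beat <- simulate_fontan(fontan_params(), delay_dT = 0)
#' beat_metrics(beat)
#' }
#' @export
simulate_fontan <- function(params = fontan_params(),
                            delayed_fraction = params$delayed_fraction,
                            delay_dT = params$delay_dT,
                            dt_ms = 0.05, out_dt_ms = 0.5,
                            min_beats = 21, max_beats = 200, tol = 1e-3,
                            on_nonconvergence = c("error", "warn")) {
  validate_fontan_params(params)
  on_nonconvergence <- match.arg(on_nonconvergence)
  if (delayed_fraction <= 0 || delayed_fraction >= 1) {
    stop("delayed_fraction must lie in (0, 1)")
  }
  if (delay_dT < 0) stop("delay_dT must be >= 0 ms")
  out_every <- out_dt_ms / dt_ms
  if (abs(out_every - round(out_every)) > 1e-9) {
    stop("out_dt_ms must be a multiple of dt_ms")
  }
  flat <- flatten_params(params, delayed_fraction, delay_dT)
  init <- initial_state(params, delayed_fraction)
  res <- simulate_circuit_cpp(flat, init, FALSE, dt_ms / 1000,
                              as.integer(round(out_every)),
                              as.integer(min_beats), as.integer(max_beats),
                              tol)
  if (!res$converged) {
    msg <- sprintf(paste0("no periodic steady state after %d beats ",
                          "(EDV drift %.3g, stroke-output drift %.3g)"),
                   res$n_beats, res$edv_drift, res$sv_drift)
    if (on_nonconvergence == "error") stop(msg) else warning(msg)
  }
  traces <- as.data.frame(res$traces)
  traces$V <- traces$V_e + traces$V_d
  beat <- structure(
    list(traces = traces,
         events = detect_events(traces, params, delay_dT),
         convergence = list(converged = res$converged, n_beats = res$n_beats,
                            edv_drift = res$edv_drift,
                            sv_drift = res$sv_drift,
                            edv_by_beat = res$edv_by_beat,
                            sv_by_beat = res$sv_by_beat),
         delayed_fraction = delayed_fraction, delay_dT = delay_dT,
         params = params, dt_ms = dt_ms, out_dt_ms = out_dt_ms),
    class = "fontan_beat")
  beat
}

# Cardiac event times (ms within the beat; t = 0 is the atrial onset).
# Valve events are read off the flow traces; ejection is taken from the first
# aortic opening to the last closure of the beat.
detect_events <- function(traces, params, delay_dT, eps = 1e-9) {
  t <- traces$t_ms
  ao_on <- traces$Q_ao > eps
  av_on <- traces$Q_av > eps
  first_last <- function(on) {
    if (!any(on)) return(c(NA_real_, NA_real_))
    c(t[which(on)[1]], t[max(which(on))])
  }
  ao <- first_last(ao_on)
  av <- first_last(av_on)
  list(atrial_onset = 0,
       vent_onset_earlier = params$PR,
       vent_onset_delayed = params$PR + delay_dT,
       av_open = av[1], av_close = av[2],
       ao_open = ao[1], ao_close = ao[2])
}

#' @export
print.fontan_beat <- function(x, ...) {
  cat("<fontan_beat> delayed fraction", x$delayed_fraction, ", dT",
      x$delay_dT, "ms;", nrow(x$traces), "samples;",
      if (x$convergence$converged) "converged" else "NOT converged",
      "after", x$convergence$n_beats, "beats\n")
  invisible(x)
}

trapz <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

#' Per-beat hemodynamic metrics
#'
#' Summarizes a converged steady-state beat. Conventions: end-diastolic volume
#' (EDV) is the total ventricular volume at the activation onset of the
#' earlier compartment; end-systolic volume (ESV) is sampled at aortic valve
#' closure; cardiac output counts forward aortic flow; the systolic window for
#' the intercompartment reverse flow runs from the earlier activation onset to
#' aortic closure; the effective end-systolic elastance is the single-beat
#' time-varying-elastance surrogate `max_t P_v(t) / (V(t) - V0_total)` with
#' `P_v` the pressure of the outflow-bearing (delayed) compartment.
#'
#' @param beat A `fontan_beat` from [simulate_fontan()].
#' @param baseline_output Per-beat forward output (ml) of the matching
#'   zero-delay baseline; required to express the reverse flow as a percent of
#'   baseline output (`reverse_flow_pct`), otherwise that field is `NA`.
#' @return A one-row data frame of class `fontan_metrics`: volumes (ml),
#'   ejection fraction (%), cardiac output (L/min) and index (L/min/m^2),
#'   pressures (mmHg), `dPdt_max` (mmHg/s), `Ees_eff` (mmHg/ml), vascular
#'   resistance indices (mmHg/(L/min/m^2), i.e. Wood units x m^2), and
#'   reverse-flow measures.
#' @export
beat_metrics <- function(beat, baseline_output = NULL) {
  stopifnot(inherits(beat, "fontan_beat"))
  tr <- beat$traces
  ev <- beat$events
  p <- beat$params
  n <- nrow(tr)
  # the first and last samples are the same cycle phase; drop the duplicate
  # endpoint for time averages
  cyc <- seq_len(n - 1)
  dt_s <- beat$out_dt_ms / 1000

  V <- tr$V
  if (max(V) - min(V) < 1e-9) stop("degenerate trace: ventricular volume is constant")
  i_ed <- which.min(abs(tr$t_ms - ev$vent_onset_earlier))
  if (is.na(ev$ao_close)) stop("no ejection detected in this beat")
  i_es <- which.min(abs(tr$t_ms - ev$ao_close))

  EDV <- V[i_ed]
  ESV <- V[i_es]
  sv_fwd <- trapz(tr$t_ms / 1000, tr$Q_ao)          # ml per beat
  CO <- sv_fwd * p$HR / 1000                        # L/min
  CI <- CO / p$BSA
  map <- mean(tr$P_art[cyc])
  mean_cvp <- mean(tr$P_cvp[cyc])
  mean_atrial <- mean(tr$P_a[cyc])
  V0_total <- p$ventricle_unit$V0 * 20

  sys_win <- tr$t_ms >= ev$vent_onset_earlier & tr$t_ms <= ev$ao_close
  rev_ml <- trapz(tr$t_ms[sys_win] / 1000, pmax(0, -tr$Q_ic[sys_win]))

  out <- data.frame(
    EDV = EDV, ESV = ESV, EF = 100 * (EDV - ESV) / EDV,
    SV_forward = sv_fwd, CO = CO, CI = CI,
    mean_cvp = mean_cvp, mean_atrial = mean_atrial,
    ESP = tr$P_d[i_es], EDP = tr$P_d[i_ed],
    SBP = max(tr$P_art), DBP = min(tr$P_art), MAP = map,
    dPdt_max = max(diff(tr$P_d) / dt_s),
    Ees_eff = max(tr$P_d / (V - V0_total)),
    PVRi = (mean_cvp - mean_atrial) / CI,
    SVRi = (map - mean_cvp) / CI,
    reverse_flow_ml = rev_ml,
    reverse_flow_pct = if (is.null(baseline_output)) NA_real_ else
      100 * rev_ml / baseline_output)
  class(out) <- c("fontan_metrics", class(out))
  out
}
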