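params <- fontan_params()
baseline <- simulate_fontan(params, delayed_fraction = 0.70, delay_dT = 0)

test_that("the AV valve pressure drop follows the Bernoulli orifice law", {
  expect_identical(av_valve_pressure_drop(0), 0)
  expect_equal(av_valve_pressure_drop(300, EOA = 5, rho = 1.06, K = 1333),
               1.06 * 300^2 / (2 * 1333 * 25))
  # quadratic: doubling the flow quadruples the drop
  expect_equal(av_valve_pressure_drop(600), 4 * av_valve_pressure_drop(300))
  expect_error(av_valve_pressure_drop(-1), "diode")
})

test_that("volume derivatives conserve total volume for arbitrary states", {
  set.seed(11)
  for (i in 1:25) {
    st <- c(runif(1, 10, 60), runif(1, 20, 90), runif(1, 15, 60),
            runif(1, 50, 130), runif(1, 250, 550), runif(1, 10, 40),
            runif(1, 5, 35), runif(1, 0, 300))
    d <- circuit_derivatives(st, runif(1, 0, 750), params,
                             av_open = i %% 2 == 0)
    expect_lt(abs(sum(d$dstate[1:7])), 1e-9)
  }
  expect_error(circuit_derivatives(c(NA, 1:7), 0, params), "non-finite")
})

test_that("an equilibrated state with closed valves has zero derivatives", {
  # build all node pressures equal to 5 mmHg in diastole (e = 0 everywhere)
  P <- 5
  st <- c(
    fontansim:::edpvr_volume(P, compartment_parameters(0.30)),
    fontansim:::edpvr_volume(P, compartment_parameters(0.70)),
    fontansim:::edpvr_volume(P, params$atrium),
    P * params$systemic$C_art, P * params$systemic$C_ven,
    P * params$pulmonary$C_art, P * params$pulmonary$C_ven, 0)
  pp <- fontan_params(delayed_fraction = 0.70)
  # t = 700 ms: all chambers relaxed
  d <- circuit_derivatives(st, 700, pp, av_open = FALSE)
  expect_equal(max(abs(d$dstate)), 0, tolerance = 1e-10)
  expect_equal(unname(d$pressures[c("P_e", "P_d", "P_a", "P_sa")]),
               rep(P, 4), tolerance = 1e-9)
})

test_that("node pressure follows P = V/C", {
  st <- c(30, 70, 30, 99, 400, 25, 20, 0)
  d <- circuit_derivatives(st, 0, params, av_open = FALSE)
  expect_equal(d$pressures[["P_sa"]], 99 / 1.1)
})

test_that("the steady-state beat is periodic, conservative and diode-clean", {
  tr <- baseline$traces
  expect_true(baseline$convergence$converged)
  # periodicity: state at the two beat boundaries agrees
  expect_lt(abs(tr$V[1] - tr$V[nrow(tr)]) / tr$V[1], 1e-3)
  # volume conservation along the whole beat
  V0_e <- compartment_parameters(0.30)$V0
  V0_d <- compartment_parameters(0.70)$V0
  stressed <- (tr$V_e - V0_e) + (tr$V_d - V0_d) + (tr$V_a - params$atrium$V0) +
    tr$P_sa * params$systemic$C_art + tr$P_sv * params$systemic$C_ven +
    tr$P_pa * params$pulmonary$C_art + tr$P_pv * params$pulmonary$C_ven
  expect_lt(max(abs(stressed - params$total_stressed_volume)), 0.05)
  # no negative forward flows across either valve
  expect_true(all(tr$Q_ao >= 0))
  expect_true(all(tr$Q_av >= 0))
})

test_that("the zero-delay baseline is fraction-invariant", {
  ref <- beat_metrics(baseline)
  for (f in c(0.20, 0.50, 0.90)) {
    b <- simulate_fontan(params, delayed_fraction = f, delay_dT = 0)
    m <- beat_metrics(b)
    expect_lt(abs(m$CO - ref$CO) / ref$CO, 0.03)
    expect_lt(abs(m$EDV - ref$EDV) / ref$EDV, 0.03)
    # compartment pressures agree up to the small communication drop Q_ic*R_ic
    expect_lt(max(abs(b$traces$P_e - b$traces$P_d)), 4)
  }
})

test_that("a near-total delayed fraction mimics a prolonged AV delay", {
  m1 <- beat_metrics(simulate_fontan(params, delayed_fraction = 0.95,
                                     delay_dT = 40))
  m2 <- beat_metrics(simulate_fontan(fontan_params(PR = 140),
                                     delayed_fraction = 0.95, delay_dT = 0))
  for (k in c("EDV", "CO", "EF", "MAP")) {
    expect_lt(abs(m1[[k]] - m2[[k]]) / abs(m2[[k]]), 0.03)
  }
})

test_that("non-convergence raises an error carrying the drift", {
  expect_error(simulate_fontan(params, max_beats = 3),
               "no periodic steady state")
  expect_warning(simulate_fontan(params, max_beats = 3,
                                 on_nonconvergence = "warn"),
                 "drift")
})

test_that("beat metrics reject degenerate traces and honour conventions", {
  m <- beat_metrics(baseline, baseline_output = 50)
  expect_true(m$EDV > m$ESV)
  expect_true(m$EF > 0 && m$EF < 100)
  expect_equal(m$reverse_flow_pct, 100 * m$reverse_flow_ml / 50)
  expect_true(is.na(beat_metrics(baseline)$reverse_flow_pct))
  # EDV is sampled at the earlier-compartment activation onset
  i_ed <- which.min(abs(baseline$traces$t_ms - params$PR))
  expect_equal(m$EDV, baseline$traces$V[i_ed])
  fake <- baseline
  fake$traces$V[] <- 100
  expect_error(beat_metrics(fake), "degenerate")
})

test_that("the compiled integrator agrees with an independent ODE solver", {
  skip_if_not_installed("deSolve")
  tr <- baseline$traces
  i0 <- which(tr$t_ms == 300)  # mid-ejection: AV closed, no valve events
  st0 <- c(tr$V_e[i0], tr$V_d[i0], tr$V_a[i0],
           tr$P_sa[i0] * params$systemic$C_art,
           tr$P_sv[i0] * params$systemic$C_ven,
           tr$P_pa[i0] * params$pulmonary$C_art,
           tr$P_pv[i0] * params$pulmonary$C_ven, 0)
  rhs <- function(t, y, parms) {
    list(circuit_derivatives(y, t * 1000, params, av_open = FALSE)$dstate)
  }
  sol <- deSolve::ode(y = st0, times = seq(0.300, 0.320, by = 0.001),
                      func = rhs, parms = NULL, method = "lsoda",
                      rtol = 1e-9, atol = 1e-9)
  i1 <- which(tr$t_ms == 320)
  expect_equal(unname(sol[nrow(sol), 2]), tr$V_e[i1], tolerance = 1e-4)
  expect_equal(unname(sol[nrow(sol), 3]), tr$V_d[i1], tolerance = 1e-4)
})

test_that("configuration round-trips through YAML", {
  path <- tempfile(fileext = ".yaml")
  p <- fontan_params(HR = 75, delayed_fraction = 0.45, delay_dT = 25)
  write_fontan_config(p, path)
  q <- read_fontan_config(path)
  expect_equal(q$HR, 75)
  expect_equal(q$delayed_fraction, 0.45)
  expect_equal(q$delay_dT, 25)
  expect_equal(q$ventricle_unit$Emax, p$ventricle_unit$Emax)
  expect_equal(q$systemic$R_art, p$systemic$R_art)
  unlink(path)
})
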