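# fontansim

Lumped-parameter (0D) simulation of mechanical dyssynchrony in the
single-ventricle (Fontan) circulation.

## The problem

After a total cavopulmonary connection, one ventricle drives both the
systemic and pulmonary beds in series. Conduction disturbance can delay the
activation of part of the ventricular wall, and because single-ventricle
anatomy is morphologically diverse, the *fraction* of the wall that is
delayed varies widely between patients. Delayed activation produces
mechanical discoordination: the early-activated wall shortens during
isovolumic contraction, then is stretched back during ejection once the
delayed wall contracts (a systolic rebound stretch). `fontansim` is for
physiologists and modellers who want to study, with a tested and fully
reproducible pipeline, how the delayed-wall fraction and the activation
delay jointly degrade hemodynamics — and how well strain-based
discoordination indices predict that degradation.

## The model

* **Chambers** follow a time-varying elastance law
  `P(V,t) = Ped(V) + e(t) (Pes(V) − Ped(V))` with linear end-systolic limb
  `Pes = Emax (V − V0)` and exponential end-diastolic limb
  `Ped = A (exp(B (V − V0)) − 1)`. The ventricle is built from 20 identical
  units; a compartment of `n` units has `Emax/n`, `B/n`, `n·V0`, so parallel
  composition is exact. The delayed compartment's activation onset is
  shifted by ΔT.
* **Circulation**: aortic valve (diode + series resistance) → systemic
  three-element Windkessel → systemic venous compartment → cavopulmonary
  junction → pulmonary Windkessel → pulmonary venous compartment → single
  atrium → Bernoulli atrioventricular valve with inertance → ventricle. The
  two ventricular compartments communicate through a small resistance whose
  flow mimics the swinging intraventricular (septal-defect) Doppler signal.
* **Strain synthesis**: the ventricle is a hemisphere; on its semicircular
  coronal outline a wall with volume fraction `v` occupies the length
  fraction `arccos(1 − 2v)/π` (equivalently `AR = (1 − cos(π·LR))/2`).
  Seven equal material segments are laid out at end-diastole and tracked;
  hemiglobal longitudinal strain on each side averages the three basal
  segments, apical cap excluded. Discoordination indices:
  `R_strains = (100 + S_ejection)/(100 + S_isovolumic)` (> 1 flags rebound
  stretch) and the time-to-peak-strain difference.
* **Clinical layer**: the contractility surrogate `estEes = AP_dic / ESVi`,
  second-order response-surface fits of log10 BNP / estEes on QRS-duration
  Z-score and delayed-wall area ratio with standardized coefficients and
  extremum localization, plus a seeded synthetic-cohort generator so the
  statistics are testable without patient data.

## Worked example

```r
library(fontansim)

params   <- fontan_params()                       # defaults: tuned 40-kg Fontan
baseline <- simulate_fontan(params, delayed_fraction = 0.70, delay_dT = 0)
round(as.data.frame(beat_metrics(baseline))[, c("EDV", "EF", "CI", "MAP",
                                                "mean_cvp", "EDP", "PVRi")], 2)
#>      EDV    EF   CI   MAP mean_cvp EDP PVRi
#> 1 102.35 51.44 3.16 91.64    10.52 8.6 1.35

dys <- simulate_fontan(params, delayed_fraction = 0.70, delay_dT = 90)
st  <- beat_strains(dys)
ev  <- dys$events
r_strains(st$earlier, st$time_ms, ev$vent_onset_earlier, ev$ao_open, ev$ao_close)
#> [1] 1.063452
time_to_peak_difference(st)
#> [1] 317.5
round(100 * (beat_metrics(dys)$CO / beat_metrics(baseline)$CO - 1), 1)
#> [1] -6.6
```

The baseline beat reproduces typical post-Fontan hemodynamics (end-diastolic
volume ≈ 102 ml, ejection fraction ≈ 52%, cardiac index ≈ 3.15
L·min⁻¹·m⁻², mean CVP ≈ 10 mmHg). Delaying activation of a 70% compartment
by 90 ms produces the discoordination phenotype: a rebound-stretch ratio
above 1 on the early-activated wall, a large time-to-peak delay, and a 6.6%
loss of cardiac output relative to that fraction's own zero-delay baseline.

The full sweep and the predictor ranking:

```r
sweep <- run_dyssynchrony_grid(params)       # 19 delays x 19 fractions
most_vulnerable_fraction(sweep, dT = 90)     # fraction with largest CO loss
#> [1] 0.7
predictor_correlations(sweep)                # Spearman rho against dEes
#>           predictor        rho   abs_rho
#> 4 r_strains_earlier -0.9079447 0.9079447
#> 1         dDpdt_pct  0.8777501 0.8777501
#> 2  reverse_flow_pct -0.7212315 0.7212315
#> 3       ttp_diff_ms -0.6451174 0.6451174
```

A ventricle whose delayed compartment holds ~70% of the volume is the most
vulnerable to a large activation delay, and the rebound-stretch ratio is
the strongest rank predictor of the simulated contractility loss.

See `vignettes/fontan-dyssynchrony.Rmd` for the model's assumptions,
numerical choices and limitations, and `?cohort_spec` /
`?fit_response_surface` for the synthetic clinical layer.

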