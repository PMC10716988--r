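---
title: "Modelling mechanical dyssynchrony in the single-ventricle circulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling mechanical dyssynchrony in the single-ventricle circulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question the package addresses

Patients with a functional single ventricle show very diverse ventricular
morphologies, and when an intraventricular conduction disturbance delays the
activation of part of the wall, the *size* of the delayed region — not only
the electrical delay itself — shapes the mechanical consequences. The
early-activated wall shortens first against a still-passive delayed wall,
then is stretched back during ejection once the delayed wall contracts (a
"systolic rebound stretch", the single-ventricle analogue of the septal
flash in left bundle branch block). `fontansim` provides a fully scripted,
reproducible environment to study this interaction: a 0D (lumped-parameter)
closed-loop model of the Fontan circulation with a two-compartment ventricle,
a strain-synthesis layer that converts compartment volumes into the
hemiglobal longitudinal strain curves an echocardiographer would measure,
discoordination indices, a systematic activation-delay-by-fraction sweep,
and a clinical-statistics layer (second-order response surfaces) exercised
on synthetic cohorts.

## The ventricular model

Each contractile chamber follows a time-varying elastance law. With
activation fraction $e(t) \in [0,1]$,

$$P(V, t) = P_{ed}(V) + e(t)\,\bigl(P_{es}(V) - P_{ed}(V)\bigr),$$

where the end-systolic relation is linear, $P_{es}(V) = E_{max}(V - V_0)$,
and the end-diastolic relation is exponential,
$P_{ed}(V) = A\,(e^{B (V - V_0)} - 1)$. The ventricle is assembled from 20
identical units; a compartment comprising $n$ units in parallel has
$E_{max}/n$, $B/n$ and $n V_0$ (with $A$, $T_{max}$ unchanged), which makes
parallel composition exact: two compartments at a common pressure always
hold the same total volume as the single assembled chamber, for both limbs
of the law. The delayed compartment receives its activation onset
$\Delta T$ ms after the earlier one.

**Activation waveform.** The waveform shape is not uniquely determined by
the published material, so the package uses the raised cosine that is
standard in this lumped-model family: a rise
$e = \tfrac12(1-\cos(\pi t/T_{max}))$ over $T_{max}$ followed by a
raised-cosine relaxation over $T_{max}/2$ (configurable through
`relax_fraction`). The choice is validated a posteriori: with the default
parameter set the simulated steady state reproduces the tuned Fontan
baseline profile (end-diastolic volume, ejection fraction, cardiac index,
venous/atrial/arterial pressures, resistance indices) within 10%.

**Negative distension** ($V < V_0$) is permitted and returns negative
pressure; small compartments genuinely reach it under paradoxical stretch.

## The closed loop

The circuit chains, in series: two-compartment ventricle → aortic valve
(ideal diode + 0.005 mmHg·s/ml series resistance) → systemic three-element
Windkessel ($Z_{sa}$, $C_{sa}$, $R_{sa}$) → systemic venous compartment
($C_{sv}$, $R_{sv}$) → cavopulmonary (TCPC) junction → pulmonary Windkessel
($Z_{pa}$, $C_{pa}$, $R_{pa}$) → pulmonary venous compartment ($C_{pv}$,
$R_{pv}$) → single atrium → atrioventricular valve → earlier ventricular
compartment. The AV valve is a Bernoulli orifice
($\Delta P = \rho Q^2 / (2 K\, \mathrm{EOA}^2)$) with inertance $L$ and
diode behaviour (the inertial state resets on closure). The two ventricular
compartments communicate only through a small resistance
($R_{ic} = 0.008$ mmHg·s/ml), whose flow is the model's analogue of the
swinging intraventricular (ventricular-septal-defect) flow seen on Doppler.
AV inflow enters the earlier compartment and aortic outflow leaves the
delayed one, which carries the outflow tract; both attachments follow the
anatomical reading of the two-compartment schematic and are deliberate,
documented choices.

**Where is "central venous pressure" measured?** The published baseline
profile is only self-consistent if CVP is read at the TCPC junction distal
to the systemic venous resistance (the superior-vena-cava site in a total
cavopulmonary connection): with the tabulated resistances and a cardiac
index of 3.15 L·min⁻¹·m⁻², the junction pressure, mean atrial pressure and
the pulmonary/systemic resistance indices then agree simultaneously with
the published values, whereas reading CVP at the venous compliance node
would force a mean atrial pressure near 2 mmHg. The package therefore
reports `P_cvp` at the junction ($P_{C_{pa}} + Z_{pa} Q$) and also records
the compliance-node pressure (`P_sv`) for inspection.

**Total stressed volume.** The conserved 720 ml counts compliance stressed
volumes plus chamber volumes *above* their unstressed volumes — the
physiologic definition. The alternative bookkeeping (chambers at absolute
volume) was evaluated and trades venous-pressure accuracy against
end-diastolic accuracy without leaving the acceptance band; the physiologic
convention is kept.

## Numerics

The loop is integrated by a compiled fixed-step 4th-order Runge–Kutta
scheme with $\Delta t = 0.05$ ms (well under the shortest time constant,
the AV-valve inertance against its Bernoulli slope, ≈ 30 ms at typical
flows). Valve diode flags are frozen across the four stages of a step and
updated between steps; forward flows are clamped non-negative. deSolve is
used in the test suite as an independent cross-check of the derivative
field over a smooth window of the beat. Integration starts from a
documented allocation (ventricle 100 ml split by the compartment fractions,
atrium 30 ml, the remaining stressed volume spread over the four
compliances at a common pressure) and runs until the end-diastolic volume
and forward stroke output both change by `<` 0.1% between successive beats
(minimum 21 beats, cap 200, error on failure carrying the last drift).
Volume conservation holds along accepted trajectories to `<` 0.05 ml out of
720. One steady-state run takes well under a second; the full 361-condition
sweep runs in about a minute on one CPU.

## Strain synthesis and discoordination indices

The ventricle is a hemisphere; a coronal cut through the vertex shows a
semicircular outline of length $\pi r(t)$ with $r = (3V/2\pi)^{1/3}$. On a
hemisphere, a wall holding the volume (= area) fraction $v$ occupies the
outline-length fraction $\mathrm{LR}(v) = \arccos(1-2v)/\pi$ — the same
identity, $\mathrm{AR} = (1-\cos(\pi\,\mathrm{LR}))/2$, that converts a
clinically measured length ratio of the delayed wall into its area ratio.
The earlier wall's arc is therefore $\mathrm{LR}(V_e(t)/V(t))$ at every
instant, applied instantaneously; within each compartment's arc the stretch
is uniform. The outline is divided into seven equal material segments at
end-diastole (the reference sample, taken at the earlier compartment's
activation onset); each material point keeps its relative position within
its compartment's arc, and segments straddling the compartment boundary are
split there. Hemiglobal strain on each side is the relative length change
of the three basal segments from that base, the apical cap excluded. At
zero delay the two curves coincide through systole; during rapid filling
they deviate transiently because the inflow enters via the earlier
compartment — a direct consequence of the series topology, excluded from
the index windows.

Two indices quantify discoordination:

* the rebound-stretch ratio
  $R_{strains} = (100 + S_{ej})/(100 + S_{ivc})$, with $S_{ivc}$ the
  minimum strain between activation onset and aortic opening and $S_{ej}$
  the minimum during ejection ($> 1$ flags a rebound stretch; the window
  start is configurable because clinical practice starts it at QRS onset,
  the model at activation onset — the same instant here);
* the time-to-peak-strain difference between the delayed and earlier
  curves (first global minimum from the end-diastolic reference,
  first-occurrence tie-breaking).

## The sweep

`run_dyssynchrony_grid()` runs every combination of activation delay (0–90
ms in 5-ms steps; 90 ms corresponds to 10 standard deviations of QRS
prolongation on the clinical scale) and delayed-compartment fraction
(5–95% in 5% steps), 361 conditions. Relative changes in cardiac output,
effective elastance and maximal pressure rise are computed against the
*same-fraction* zero-delay baseline, because the baseline is only
approximately fraction-invariant. The effective end-systolic elastance is
the single-beat surrogate $\max_t P_v(t)/(V(t) - V_{0,tot})$ with $P_v$ the
outflow-compartment pressure; only relative changes of it are interpreted,
so any monotone-consistent definition serves. The systolic reverse-flow
measure integrates the delayed-to-earlier intercompartment flow from the
earlier activation onset to aortic closure and is expressed as a percent of
the baseline per-beat output. Non-convergent conditions are flagged rather
than fatal, and rows are sorted by (delay, fraction) so results cannot
depend on execution order.

## The clinical layer and the synthetic cohort

`est_ees()` implements the catheterization contractility surrogate
(dicrotic-notch aortic pressure over indexed end-systolic volume);
`fit_response_surface()` fits the five-term second-order polynomial in QRS
Z-score and delayed-wall area ratio by ordinary least squares, centering the
quadratic and cross terms at the sample means, with standardized
coefficients obtained by z-scoring the response and each constructed term
(z-scoring the raw variables *before* term construction is available behind
the `standardize` flag, since the published table does not say which
convention was used; the two agree in sign). `extremum_ar_at()` returns the
vertex of the fitted quadratic in the area ratio at a fixed Z-score,
clipping to the observed range rather than extrapolating. p-values are
classical OLS t-tests without multiplicity correction, matching the
clinical analysis being emulated.

The synthetic generator emulates the published cohort structure without any
patient data: QRS Z-scores follow a log-normal shifted by the inclusion
threshold of 2, calibrated in closed form to the published median (3.8) and
IQR width (2.5–6.2); matching all three quantiles would overdetermine the
two parameters, so the achieved quartiles are 2.73/6.44. The area ratio is
a scaled beta (mean 57.2%, SD 20%) spanning roughly 5–95%. QRS Z-score and
area ratio are drawn independently because their clinical correlation is
unreported (a correlation can be imposed by editing the spec). Both
response surfaces are phenomenological second-order polynomials with
Gaussian noise, their extrema planted at an area ratio of 62% (BNP maximum)
and 68% (elastance minimum) at a QRS Z-score of 10, and their linear terms
carrying the clinically observed signs. The noise SDs (0.20 on log10 BNP,
0.15 on the elastance) are the generator's contract with the analysis
layer: they are calibrated so that the fit-and-locate loop recovers the
planted extremum within ±5 area-ratio points at n = 62 in at least 95% of
replicates. This makes the synthetic surfaces cleaner (higher $R^2$) than
typical clinical data, where the corresponding quadratic terms are only
marginally significant — so passing that recovery loop demonstrates the
correctness of the pipeline, not that a 62-patient clinical cohort would
localize its extremum that precisely. BNP noise acts on the log scale;
elastance noise is linear-scale and floored at a small positive value.

## Design notes and limitations

* The interface is the R functions plus `scripts/acceptance.R`; no shell
  CLI is shipped because every consumer of this package works from R
  scripts, and the YAML configuration reader/writer covers interchange.
* No pressure/flow wave propagation (0D by construction), no baroreflex, no
  Glenn variant, and acute responses only — chronic remodeling of the
  early-activated wall is outside the model.
* The hemispherical geometry with instantaneous area-fraction mapping is
  one defensible reading of an under-specified construction and is isolated
  behind `hemiglobal_strains()`; a different compartment-shape model would
  replace only that function.
* The series inflow/outflow attachment makes the intercompartment flow
  carry the whole transit flow, so it is never literally zero at zero
  delay; the compartment pressure difference stays within a few mmHg
  (flow × 0.008) and the zero-delay hemodynamics are fraction-invariant to
  within ~1–2%.
* Problem sizes used throughout the tests and the acceptance script: one
  beat at 0.05-ms steps with 0.5-ms output sampling, the full 19 × 19
  sweep, and 200 replicate cohorts of n = 62 for the recovery loop.
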