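---
title: "Photothermal dosimetry with pttdose: models, methods, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Photothermal dosimetry with pttdose}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(pttdose)
```

## The problem

Photothermal therapy (PTT) uses a near-infrared laser and a light-absorbing
nanomaterial to heat tumor tissue to cytotoxic temperatures. Quantitative
analysis of such experiments revolves around three linked questions:

1. **How good a heater is the material?** — the photothermal conversion
   efficiency (PCE, $\eta$), estimated from cuvette heating/cooling curves.
2. **How much thermal damage did a treatment deliver?** — the cumulative
   equivalent minutes (CEM) thermal dose integrated from the recorded
   temperature history.
3. **Did the treatment work?** — caliper-based tumor trajectories,
   regression/progression classification, and Kaplan–Meier survival.

`pttdose` implements all three stages plus seeded synthetic-data generators,
so the complete pipeline can be validated end to end against known ground
truth without any instrument data.

## The lumped energy-balance model

A cuvette (or a small subcutaneous tumor) under laser irradiation is treated
as a single thermal lump at temperature $T(t)$, exchanging heat with an
environment at $T_{env}$ through a heat-loss coefficient $hS$ (heat transfer
coefficient $\times$ irradiated surface area, W K$^{-1}$):

$$\sum_i m_i c_{p,i}\,\frac{dT}{dt}
  = \eta P\left(1 - 10^{-A_\lambda}\right) + \dot Q_0 - hS\,(T - T_{env}),$$

where $m_i, c_{p,i}$ are the masses and specific heats of the components
(holder, carrier liquid, nanomaterial), $P$ is the laser power, $A_\lambda$
the sample absorbance at the laser wavelength, and $\dot Q_0$ the nonspecific
power absorbed by holder and carrier alone. With constant coefficients the
solution is a single exponential with relaxation time

$$\tau_s = \frac{\sum_i m_i c_{p,i}}{hS},$$

a steady state $T_{max} = T_{env} + [\eta P (1-10^{-A_\lambda}) + \dot
Q_0]/hS$, and, after laser-off, a cooling law conveniently written through
the dimensionless temperature
$\Theta(t) = (T_{env} - T(t))/(T_{env} - T_{max}) = e^{-t/\tau_s}$.

`simulate_trace()` integrates this model with the **exact per-segment
exponential update** $T(t{+}\Delta t) = T_{ss} + (T(t) - T_{ss})
e^{-\Delta t/\tau_s}$ rather than an Euler step. The noise-free trace is
therefore free of discretization error at any sampling interval, which lets
the fitting tests isolate the effect of measurement noise alone. Gaussian
camera noise is added after the noise-free solution, so a given seed yields
bit-identical traces.

Temperatures are handled in degrees Celsius throughout; every model equation
uses temperature *differences*, for which °C and K coincide.

### Photobleaching

Organic near-infrared dyes can photobleach: the heating curve peaks and then
sags as the absorber degrades. The package models this phenomenologically as
first-order decay of the specific absorbed term with accumulated laser-on
time, $\eta P(1-10^{-A_\lambda})\,e^{-k_b t_{on}}$, with `bleach_rate`
$k_b = 0$ (photostable) by default. Only the thermal signature is modeled,
not the photochemistry. A bleached trace fails the steady-state guard in the
PCE workflow, mirroring the experimental practice of not quoting a PCE for a
photobleaching sample.

### The 55 °C session controller

In vivo, the operator caps the tumor surface temperature (55 °C here,
at the boundary between moderate ablation and overly aggressive heating) by
turning the laser power down when the cap is reached. The control law is not
standardized, so `simulate_session()` formalizes it as: **on a threshold
crossing, attenuate the applied power by factors of $(1 -$ `step_down`$)$
until the steady state implied by the current power is at or below the
threshold; never restore power.** Two properties follow and are enforced by
tests:

* the applied power trace is monotone non-increasing;
* the noise-free temperature never exceeds
  `threshold` $+ (\Delta t/\tau_s)(T_{ss,max} - {}$`threshold`$)$ — the
  one-step rise bound — because after the capping action the temperature can
  only relax downward.

A plausible alternative — one fixed 10% cut per sample while above
threshold — was rejected: when one cut leaves the implied steady state above
the threshold the temperature keeps climbing for several samples and the
bound above fails; when many cuts accumulate during the relaxation back
below threshold, the session sags far under the cap instead of holding
"around" it. The chosen law holds capped sessions within a few degrees below
the cap, which is also what published session profiles look like.

## PCE estimation from the cooling regime

`estimate_pce_experiment()` chains four steps, each available separately:

1. **`fit_cooling()`** — nonlinear least squares of
   $T(t) = T_{env} + (T_{max}-T_{env})e^{-(t-t_{off})/\tau_s}$ on the
   laser-off tail, with $\tau_s$ the *only* free parameter. $T_{env}$ is
   pinned from the pre-laser baseline (or a user override) and $T_{max}$
   from the mean of the last `tail_frac` (default 0.1) of the laser-on
   samples. Fitting raw temperatures rather than $\log\Theta$ avoids the
   bias that additive noise induces after log transformation, where the
   late, near-zero tail turns into wildly asymmetric log residuals.
2. **`infer_hS()`** — $hS = \sum_i m_i c_{p,i} / \tau_s$.
3. **`estimate_q0()`** — the same fit on a blank (nanomaterial-free) record
   gives $\dot Q_0 = hS_{blank}(T_{max,blank} - T_{env})$. The blank must
   have plateaued: the slope over the last 60 s of heating must be below
   0.005 °C s$^{-1}$ (both configurable). The same guard is applied to the
   sample trace, which is what rejects photobleaching runs.
4. **`compute_pce()`** —
   $\eta = [hS(T_{max}-T_{env}) - \dot Q_0]\,/\,[P(1-10^{-A_\lambda})]$.
   Estimates outside $[0,1]$ are *flagged*, never clipped.

Defaults that matter: `settle = 5` s of post-laser-off data are discarded
(convection/camera transients); the cooling window needs at least 5 samples;
a steady-state rise below `min_delta = 0.5` °C is rejected as insufficient
signal rather than fitted. The sample and blank are assumed to share the
same holder geometry and hence the same $hS$ functional form; this is the
standard cuvette assumption and is stated rather than estimated.

`correct_absorbance()` applies the Beer–Lambert dilution correction and
warns above $A = 1$, where spectrophotometer linearity commonly degrades.

## Thermal dose

The dose at reference temperature $T_{ref}$ is

$$\mathrm{CEM}_{T_{ref}} \;=\; \sum_{\text{intervals}}
  R^{\,T_{ref} - \bar T}\,\Delta t \quad [\text{minutes}],$$

with $\bar T$ the mean of the two samples bounding each interval
(trapezoid-style; the defining sum leaves the within-interval rule open) and
the cell-death rate constant $R$ piecewise: `R_above` when $\bar T$ exceeds
the breakpoint, `R_below` at or below it (ties take the sub-breakpoint
branch). Both branches give $R^0 \Delta t$ at the breakpoint, so the dose is
continuous there.

`cem50_spec()` uses the tabulated ablative-regime constants 0.51 / 0.27 at
the 50 °C reference; `cem43_spec()` the classical 0.5 / 0.25 at 43 °C. Note
a deliberate inconsistency in the literature's own constants: the
temperature-independent activation-energy relation $R_{50} = R_{43}^{0.9575}$
(provided as `convert_rate_constant()`) gives 0.515 and 0.2652, which the
tabulations round to 0.51 and 0.27. The `dose_spec` defaults follow the
tabulated (printed) constants; the conversion function reproduces the power
law exactly.

CEM43 and CEM50 are always integrated directly from the trace rather than
scalar-converted from each other: the scalar conversion is exact only for
traces confined to one branch of $R$. `group_dose_stats()` summarizes doses
per experimental group and runs two-sided Welch tests between groups
(significance at 0.05), since dose variances are not assumed equal between
groups of different tumor composition.

## Tumor response and survival

`tumor_volume()` implements the ellipsoidal caliper formula
$V = D d^2/2$ (mm³); `is_eligible()` applies the enrolment window,
inclusive at both ends (50 and 150 mm³ enrol — the boundary semantics are a
documented package decision, as "within 50–150 mm³" does not fix them).

`classify_outcome()` turns a trajectory into a label using a detection-style
threshold (default 5 mm³ — about the smallest palpable caliper volume, since
"complete regression" is reported in practice without a numeric criterion)
and a confirmation count (default 2 consecutive measurements):
`complete_regression` (ends in a confirmed sub-threshold run),
`recurrence` (confirmed regression, then ≥ 2 consecutive rises back above),
`progression` (never below threshold, final above initial volume), else
`non_evaluable` (e.g. an early unexplained death with fewer than two
post-treatment measurements). Labels depend only on the ordered volume
sequence, so they are invariant to rescaling the measurement days and to
appending further confirmed sub-threshold measurements.

This bookkeeping intentionally separates regression counting from survival:
an early unexplained death is `non_evaluable` for regression but still an
event for `km_survival()`, reproducing the common "11/12 regressions,
85% (11/13) survival" style of reporting — 13 treated animals, two events
(one death, one late sacrifice), survival $\frac{12}{13}\cdot\frac{11}{12} =
11/13 \approx 84.6\% \to 85\%$ at the 120-day horizon. `km_survival()`
delegates the product-limit computation to `survival::survfit()`; deaths and
sacrifices are events, animals alive through follow-up are censored at the
horizon. Day indexing follows the study design: administration day −5,
treatment day 0, follow-up through day 120.

## The synthetic-data generators

`gen_experiment()` emulates the cuvette protocol: 0.5 g of aqueous
dispersion, 965 mW at 808 nm, a 30 s pre-laser baseline, 90 min of heating
(≈ 22 relaxation times, so the plateau is genuinely stationary), 10 min of
cooling, 1 Hz sampling, 0.2 °C camera noise. The default $hS$ makes
$\tau_s = 248$ s and the default $\dot Q_0 = 0.03$ W heats the blank by
≈ 3.6 °C. The blank shares holder, $hS$ and $\dot Q_0$ with the sample and
has $\eta = 0$. The camera frame rate and the in vivo role of $\dot Q_0$ are
not fixed by published protocols; the package defaults to 1 Hz and uses
$\dot Q_0$ in vitro only (cohort sessions set it to 0).

`gen_cohort()` emulates the preclinical design: group sizes default to
4 control, 4 GF (females), 5 GFL (losartan-pretreated females), 4 GM
(males) — 13 treated animals. (Published group counts for the male group
vary between 4 and 5 within the same report; 4 is the reading consistent
with the 11/12 and 11/13 outcome bookkeeping.) Per animal:

* enrolment volume uniform in the eligibility window 50–150 mm³;
* tumor heterogeneity enters through a log-normal absorbed laser power
  (`uptake_mean = 0.34` W, `uptake_cv = 0.25`) — through absorbed power
  *only*, not $hS$, to keep the recovery tests identifiable;
* the 15-min session is simulated with the 55 °C controller on a 0.42 J K⁻¹
  tumor lump with $hS = 0.015$ W K⁻¹ ($\tau_s = 28$ s, fast in vivo
  relaxation through perfused tissue) above a 32.5 °C skin baseline;
* CEM50 is integrated from the session trace; the probability of complete
  regression follows a logistic link in log dose,
  $p = \operatorname{logit}^{-1}[(\ln \mathrm{CEM50} - \ln
  \mathrm{dose50})/\mathrm{slope}]$ with `dose50 = 60` min and
  `dose_slope = 0.5`;
* regressors decay exponentially (0.3 day⁻¹) to below the caliper detection
  limit; non-regressors and controls grow exponentially (half of / exactly
  0.25 day⁻¹) and are sacrificed above 2000 mm³; caliper axes carry 3%
  log-normal measurement error at a fixed 0.8 aspect ratio.

The **dose–response link and its defaults are package inventions for
testability**: no quantitative dose–response was established by the study
the defaults emulate, and none should be read into synthetic cohorts. The
uptake scale was calibrated once so that the large-cohort mean CEM50 falls
in the 100–160 min range of reported group means, with session peaks in the
observed 44–55 °C band; it is a study-condition setting, not a fitted
parameter. Tumor kinetics are deliberately the simplest exponential
grow/decay pair — adequate for exercising the classifier, not a growth
model.

What the generators do *not* emulate — and hence what passing tests cannot
show about real data: spatial temperature gradients across the tumor (the
lump has one temperature; real infrared ROIs average a surface field),
perfusion changes during ablation, pharmacokinetic uptake dynamics,
immune-mediated abscopal effects on the growth curve, correlated camera
noise, and operator variability in the power tuning.

## Numerical choices and degenerate inputs

* One-dimensional least squares for $\tau_s$ uses `stats::optimize` on a
  wide bracket with a $10^{-7}$ s absolute tolerance — the objective is
  smooth and unimodal in $\tau_s$ for anchored $T_{env}, T_{max}$.
* Exact-update simulation makes $hS \tau_s \equiv \sum m_i c_{p,i}$ an
  algebraic identity, which the tests assert.
* Degenerate inputs are classed errors, not NA results: no cooling tail,
  fewer than 5 usable cooling points, a flat "cooling" signal, a
  non-plateaued blank, $T_{max} = T_{env}$ in $\Theta$, $A_\lambda = 0$ in
  the PCE formula, and empty dose windows all raise typed conditions.
* At the dose breakpoint the sub-breakpoint constant applies (ties go
  below); intervals are weighted by their actual $\Delta t$, so irregular
  sampling is handled.
* Problem sizes in the test suite: 90-min 1 Hz experiments (≈ 6000 samples
  per trace), 20 seeds per ground-truth efficiency, cohorts of 13–200
  animals with 15-min 1 Hz sessions — small enough to run the whole suite
  in well under a minute while leaving the recovery criteria statistically
  meaningful.

## Known limitations

* The lumped model is zero-dimensional; it cannot represent the
  surface-versus-core temperature difference of a real tumor, so in vivo
  $\eta$-like quantities are effective, not intrinsic, parameters.
* $\dot Q_0$ is treated as proportional to applied power when the
  controller attenuates it; for strongly wavelength- or convection-dependent
  holders this is an approximation.
* The outcome classifier is threshold-based and deterministic; it does not
  model measurement-noise-induced label uncertainty near the threshold.
* Welch tests are provided for group dose comparisons; no multiplicity
  correction is applied by default because the intended use is a handful of
  pairwise group contrasts, reported alongside their p-values.
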