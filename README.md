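# pttdose

Quantitative analysis of nanoparticle-mediated **photothermal therapy
(PTT)** experiments, for researchers characterizing photothermal agents in
cuvette experiments and running preclinical treatment studies.

The package covers the three linked stages of PTT dosimetry:

1. **Photothermal conversion efficiency (PCE).** A sample under a laser of
   power *P* is modeled as a thermal lump obeying the energy balance

   Σᵢ mᵢ c₍p,i₎ dT/dt = η P (1 − 10^(−A_λ)) + Q̇₀ − hS (T − T_env),

   whose laser-off solution is a single exponential, Θ(t) = e^(−t/τₛ) with
   Θ = (T_env − T)/(T_env − T_max) and τₛ = Σ mᵢ c₍p,i₎ / hS. Fitting the
   cooling tail gives τₛ, hence hS, and the efficiency follows from the
   steady state:

   η = [hS (T_max − T_env) − Q̇₀] / [P (1 − 10^(−A_λ))],

   with the nonspecific power Q̇₀ measured on a blank.

2. **Thermal dose.** Temperature histories are reduced to cumulative
   equivalent minutes at a reference temperature,
   CEM = Σ R^(T_ref − T̄) Δt, with the piecewise cell-death rate constant R
   (ablative CEM50: 0.51 above / 0.27 at-or-below 50 °C; classical CEM43:
   0.5 / 0.25), plus per-group summaries with Welch tests.

3. **Tumor response.** Ellipsoidal caliper volumetry (V = D d²/2),
   eligibility filtering, reproducible regression/recurrence/progression
   classification over the follow-up, and Kaplan–Meier survival.

A forward simulator (`simulate_trace()`, `simulate_session()`) implements
the same energy balance with an exact exponential integrator, a
phenomenological photobleaching mode, and the 55 °C feedback power
controller used in capped in vivo sessions. Seeded generators
(`gen_experiment()`, `gen_cohort()`) produce complete synthetic experiments
and cohorts with known ground truth, so the entire pipeline is testable
without instrument data.

## Worked example

Estimate the conversion efficiency of a synthetic cuvette experiment whose
ground truth is η = 0.30 (965 mW, A = 1, 90 min heating, 10 min cooling,
0.2 °C camera noise):

```r
library(pttdose)

cfg    <- synth_experiment_config(true_eta = 0.30, seed = 42)
exp    <- gen_experiment(cfg)
system <- thermal_system(cfg$components, heat_loss = cfg$hS,
                         ambient = cfg$T_env)
estimate_pce_experiment(exp$sample_trace, exp$blank_trace, system,
                        P = cfg$P, A_lambda = cfg$A_lambda)
#> <pce_result> eta = 0.3006 (in range)
#>   dissipated = 0.2906 W, Q0 = 0.02952 W, P = 0.965 W, 1-10^-A = 0.9
#>   tau_s = 247.9 s, hS = 0.008443 W/K
```

The cooling fit recovers the relaxation time (truth: 248 s), the blank
yields the nonspecific power (truth: 0.03 W), and the energy balance returns
the efficiency within noise (truth: 0.30).

Simulate a treated cohort, dose one animal's 15-min capped session, and
summarize outcomes:

```r
cohort <- gen_cohort(synth_cohort_config(seed = 42))
dose_summary(cohort$sessions[["GF-01"]], list(cem50_spec(), cem43_spec()))
#>   T_ref R_above R_below breakpoint  cem_min time_above_breakpoint_min max_temp_C
#> 1    50    0.51    0.27         50   308.66                      14.6   55.48467
#> 2    43    0.50    0.25         43 43235.85                      14.8   55.48467

group_dose_stats(split(cohort$doses$cem50_min, cohort$doses$group))
#> <dose_group_stats>
#>  group n      mean        sd sd_defined
#>     GF 4 148.93698 126.18799       TRUE
#>    GFL 5  88.61239  86.93086       TRUE
#>     GM 4 113.10606 139.17432       TRUE
#> pairwise Welch tests:
#>  group1 group2  statistic       df   p_value significant
#>      GF    GFL  0.8139906 5.153313 0.4516095       FALSE
#>      GF     GM  0.3814559 5.943336 0.7161293       FALSE
#>     GFL     GM -0.3072827 4.813290 0.7714764       FALSE

treated <- Filter(function(r) r$group != "control", cohort$records)
km_survival(treated, horizon = 120)
#> <km_result> n = 13, events = 7, survival = 46% at horizon
```

This seed's session for animal GF-01 spent 14.6 of its 15 minutes above
50 °C, delivering 309 equivalent minutes at 50 °C (the same history
expressed at the 43 °C reference is enormous — ablative traces always are).
Group mean doses are statistically indistinguishable at these group sizes,
and 6 of the 13 treated animals regressed completely under the default
synthetic dose–response link — a deliberately middling calibration so that
both outcomes are exercised.

A shell interface wrapping the same functions is installed at
`inst/cli/pttdose` (subcommands `synth-experiment`, `synth-cohort`,
`simulate`, `fit-pce`, `dose`, `tumor`, `survival`; every run emits a JSON
log line with its parameters and seed).

## Package layout

* `R/thermal-system.R`, `R/simulate.R` — lumped model, laser schedules,
  exact-update simulation, session controller
* `R/pce.R` — cooling fit, hS/Q0 inference, efficiency estimation
* `R/dose.R` — CEM integration, rate-constant conversion, group statistics
* `R/tumor.R` — volumetry, outcome classification, Kaplan–Meier survival
* `R/synth.R` — synthetic experiment and cohort generators
* `R/io.R`, `R/cli.R` — trace/table CSV round-trips and the CLI
* `vignettes/photothermal-dosimetry.Rmd` — models, assumptions, design
  choices, and limitations in detail
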