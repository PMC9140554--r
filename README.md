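# pepower

Bayesian comparison of two field-test predictors of children's lower-limb
peak power: raw countermovement-jump (CMJ) height versus a
**potential-energy index** that also carries the child's body mass.

Raw jump height penalises heavier children — they may reach a lower height
while producing more mechanical power. The index

> PE<sub>CMJ</sub> = m · g · h<sub>flight</sub>

(mass m in kg, local gravity g = 9.79 m·s⁻² by default, flight height
h = g·t²/8 from the photocell-measured flight time t) rescores the jump by
the energy actually imparted. The package asks, with a fully specified
Bayesian regression, which of the two scores better predicts peak power
(PP) as estimated by two published linear equations, overall and within
BMI-defined weight-status groups:

```
y_i ~ Normal(mu_i, sigma)
mu_i = alpha + b1*Age + b2*Sex + b3*BMI_group + b4*Predictor
       + b5*Predictor:BMI_group
alpha ~ Student-t(3, 0, 2);  each b ~ Normal(0, 2)
sigma ~ half-Student-t(3, 0, 2)
```

Outcome, predictor and age are z-scored; sex and the three BMI-group
indicators (underweight = reference) are 0/1 dummies; four models cross
the two outcomes with the two predictors. Everything needed is
implemented in the package: field-test metric derivations, an adaptive
Metropolis-within-Gibbs sampler with whitened scalar updates,
rank-normalized split R-hat / bulk ESS diagnostics, Bayesian R², PSIS-LOO
(ELPD, LOOIC, Pareto-k, exact-refit fallback), paired ELPD differences,
per-group conditional slopes, and a synthetic-cohort generator calibrated
to the study sample's descriptive table (815 children, ages 6–11, four
BMI groups).

## Worked example

```r
library(pepower)

cohort  <- generate_cohort(cohort_config(n_subjects = 300, rng_seed = 42))
metrics <- derive_metrics(cohort)
fit     <- fit_power_model(metrics, outcome = "pp_duncan",
                           predictor = "pe_cmj", seed = 1)
evaluate_fit(fit)
#> model: pp_duncan ~ pe_cmj
#>   R2   0.90 (0.88, 0.92)
#>   elpd -85.7 +/- 19.9   looic 171.4 +/- 39.7
#>   alpha                0.31 (  0.04,   0.59)
#>   ...
#>   b_pred               1.23 (  0.86,   1.60)
#>   sigma                0.32 (  0.29,   0.34)
```

The potential-energy index explains ~90% of the variance in this
synthetic cohort's Duncan-equation peak power (R² 0.90), with a strong
conditional slope in every BMI group (`evaluate_fit(fit)$slopes$summary`
gives posterior means 1.23/1.07/0.90/0.87 from underweight to obese, all
with 95% intervals well above zero). `run_experiment()` runs all four
models and reports the two paired ELPD differences with the
potential-energy model in the favoured position — positive values mean
the mass-aware index predicts peak power better than raw jump height.

The full analysis is laid out as numbered drivers:

```sh
Rscript analysis/01_simulate_cohort.R   # calibration cohort -> results/cohort.csv
Rscript analysis/02_derive_metrics.R    # metrics, descriptives, z-score trend
Rscript analysis/03_fit_and_evaluate.R  # 4 models, diagnostics, comparisons
Rscript analysis/04_figures.R           # slope and trend figures
```

On the seeded synthetic cohort this prints `elpd_diff = 518.4 ± 33.7`
(Duncan outcome) and `896.5 ± 34.9` (Gomez outcome): the potential-energy
model is decisively favoured for both, the study's central claim
reproduced in silico.

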