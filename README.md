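# tumordyn

Bayesian modeling of tumor growth and treatment response in longitudinal
preclinical studies.

`tumordyn` is for modelers and quantitative biologists analyzing
tumor-volume time courses from treated-animal cohorts — typically a handful
of measurements per animal (here days 0, 7, 14) across an untreated control
arm and several combination-therapy arms. It fits a family of nested
logistic-growth models with dosed treatment terms, selects among them by
BIC, quantifies parameter influence by Sobol sensitivity analysis, and
predicts individual day-14 outcomes and responder status three different
ways. Because such datasets are rarely public, a synthetic-cohort generator
with known ground truth is part of the package and backs all of its
calibration tests.

## The model

All fits use constrained cases of one ODE for tumor volume *N(t)* (mm³):

    dN/dt = r N (1 − N/K) − N Σᵢ αᵢ exp(−β(t − τᵢ)) H(t − τᵢ)

with proliferation rate *r*, carrying capacity *K*, per-dose death rates
*αᵢ*, treatment-effect decay *β*, and dose-interval start times *τᵢ*
(defaults: days 0 and 7; H(0) = 1). The four named cases — `logistic`
(untreated), `linear` (β = 0, α₁ = α₂), `expdecay` (β free), `cumulative`
(β = 0, α₁ ≠ α₂) — are fitted by an affine-invariant ensemble MCMC sampler
under uniform priors, with a hierarchy that mirrors the study design:
population-level *K* (estimated on the control arm, then fixed),
protocol-level *β*, mouse-level *r*, *α*, *N₀*, σ. The `cumulative` model
defines the treatment resistivity α₁/α₂ — how much less effective the
second dose interval is than the first — which the group-informed
prediction scheme feeds back into individual forecasts.

See the methods vignette (`vignettes/tumordyn-methods.Rmd`) for the full
account of priors, numerics, the three prediction schemes and the
generator's design.

## Worked example

Generate a two-arm synthetic study, fit the control arm to fix *K*, then
fit the constant-effect treatment model to the treated arm:

```r
library(tumordyn)

cfg <- cohort_config(group_sizes = c(control = 8, T1 = 18),
                     responder_fraction = c(control = 0, T1 = 1/3),
                     resistivity_truth = c(control = 1, T1 = 1),
                     seed = 42)
gen <- generate_cohort(cfg)
cohort <- apply_sacrifice_rule(gen$cohort)   # 1000 mm^3 sacrifice rule

ctrl <- tumor_fit(cohort[cohort$group == "control", ], "logistic",
                  mcmc = mcmc_control(n_samples = 2000, seed = 1))
print(ctrl)
#> Tumor growth model fit: logistic
#>   mice: 8   observations: 24   estimated parameters (Z): 25
#>   chains: 50   steps: 21336   retained/chain: 16002   [convergence flagged]
#>   max log-likelihood: -117.391   BIC: 314.23
#>   shared K posterior median: 884.6

K   <- control_K(ctrl)                       # fix K downstream
pri <- r_prior_from_control(tumor_priors(), ctrl)

fit <- tumor_fit(cohort[cohort$group == "T1", ], "linear",
                 priors = pri, K = K,
                 mcmc = mcmc_control(n_samples = 2000, seed = 2))
fit_quality(fitted(fit)$observed, fitted(fit)$fitted)
#> CCC = 0.9906   PCC = 0.9917   MAPE = 22.14%   (n = 54 pairs)
```

The fitted posterior medians track the measured volumes almost on the
identity line (CCC/PCC ≈ 0.99 over all 54 mouse-days). The MAPE is
inflated by mice whose tumors shrank to a few mm³, where the 20 mm³
measurement noise is large in relative terms. Classifying each mouse by
whether its predicted day-14 median lies below its day-0 volume recovers
every injected responder label in this cohort:

```r
#> responder accuracy: 100.00%
```

(The convergence flag reports that some chains are shorter than 50
integrated autocorrelation times — expected with three points per mouse,
where *r* and *α* are identified mainly through their difference; see the
vignette.)

From here, `tumor_fit(..., "expdecay")` plus `select_model()` reproduces
the BIC comparison between constant and decaying treatment effects,
`sobol_time_resolved()` ranks parameter influence over time,
`predict_arm()` runs the mouse-specific / leave-one-out / group-informed
prediction schemes, and `run_pipeline()` executes the whole workflow into
a directory of CSV artifacts.

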