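---
title: "Modeling tumor growth and treatment response with tumordyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling tumor growth and treatment response with tumordyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model family

`tumordyn` models longitudinal tumor-volume measurements from preclinical
combination-therapy studies. All four models are constrained cases of one
ordinary differential equation for the tumor volume $N(t)$ (mm$^3$):

$$\frac{dN}{dt} = r N \left(1 - \frac{N}{K}\right)
  - N \sum_{i=1}^{n} \alpha_i \, e^{-\beta (t - \tau_i)} H(t - \tau_i),$$

with proliferation rate $r$ (d$^{-1}$), carrying capacity $K$ (mm$^3$),
per-dose-interval death rates $\alpha_i$ (d$^{-1}$), treatment-effect decay
rate $\beta$ (d$^{-1}$), dose-interval start times $\tau_i$ (days), and the
Heaviside step $H$ with $H(0) = 1$: a dose acts from its start time
inclusive, reflecting that treatment is delivered throughout the interval
between consecutive measurements. The named cases are:

| model | $\beta$ | $\alpha_1$ | $\alpha_2$ | use |
|---|---|---|---|---|
| `logistic` | 0 | 0 | 0 | untreated control arm |
| `linear` | 0 | $\alpha$ | $\alpha$ | constant treatment effect |
| `expdecay` | free | $\alpha$ | $\alpha$ | decaying treatment effect |
| `cumulative` | 0 | free | free | dose-specific effect |

The models are deliberately treatment-agnostic: a dose interval carries only
its start time, and the drug composition of an arm is a label. This is the
appropriate resolution for studies with three volume measurements per
animal (days 0, 7, 14) and two dose intervals (starting days 0 and 7),
where mechanistic pharmacokinetics cannot be identified.

## Numerics

Trajectories are solved by fixed-step fourth-order Runge-Kutta. The solver
restarts exactly at every dose time, so no step straddles a hazard
discontinuity and the method retains its full order between breakpoints.
The default step is 0.01 d, at which the logistic solution matches the
closed form to relative error below $10^{-6}$ over 14 days everywhere in
the prior box (the test suite verifies a 27-point grid). Likelihood
evaluations inside MCMC use a 0.25 d step; at that step the solver error
(relative error about $10^{-8}$ on the logistic case) is orders of
magnitude below the measurement noise and far below the posterior width, so
it has no measurable effect on inference while cutting cost 25-fold.
Volumes are clipped at zero, which the continuous equation never crosses;
a zero state is absorbing. The solver is vectorized across parameter sets,
which is what makes the ensemble sampler and the Saltelli designs cheap:
one call integrates every proposal (or design row) simultaneously.

# Inference

The likelihood is additive Gaussian on the measurement scale,

$$\ln \pi(D \mid \theta) = -\tfrac12 \sum_{i=1}^{N_T}
  \left[\ln(2\pi) + \ln \sigma^2 +
  \frac{(D_i - Y_i(\theta))^2}{\sigma^2}\right],$$

and all parameters carry independent uniform priors: for treated arms
$N_0 \sim U(0, 600)$ mm$^3$, $r \sim U(0.03, 0.3)$ d$^{-1}$,
$\alpha \sim U(0, 0.3)$ d$^{-1}$, $\beta \sim U(0, 2)$; for the control arm
$r \sim U(0, 0.5)$ d$^{-1}$, $K \sim U(1, 3000)$ mm$^3$,
$N_0 \sim U(0, 600)$ mm$^3$. Prior predictive checks (below) support these
boxes. The hierarchy mirrors the study design: $K$ is a population-level
parameter estimated jointly with mouse-specific $(r, N_0)$ on the control
arm and then fixed at its posterior median for every treated-arm fit —
fixing rather than propagating $K$ trades a small amount of uncertainty
quantification for identifiability with three points per mouse. $\beta$ is
protocol-level (one per arm, shared across its mice); $r$, $\alpha$ (or
$\alpha_1, \alpha_2$) and $N_0$ are mouse-level. Treated-arm $r$ bounds are
tightened to the central 95% interval of the pooled control posterior
(`r_prior_from_control()`); the percentile choice is ours and configurable.

Three design points deserve explanation:

* **The noise s.d. is estimated.** The likelihood contains $\sigma$ but no
  external estimate of it exists, so each mouse's $\sigma$ is sampled with
  a flat $U(1, 200)$ mm$^3$ prior and counted in the parameter total $Z$.
  The lower bound of 1 mm$^3$ is far below any plausible MRI segmentation
  error; the upper bound exceeds any plausible error for tumors in the
  enrollment range.
* **Day 0 is data.** The day-0 measurement enters the likelihood as a noisy
  observation of $N_0$ (with its $U(0, 600)$ prior) rather than being used
  as an exact initial condition; all three time points therefore contribute
  to the sum.
* **Sampling is by an affine-invariant ensemble.** The posterior is sampled
  with the Goodman-Weare stretch move, using $2n$ walkers for $n$ free
  parameters and a target number of retained post burn-in samples per
  walker (package default 20,000; reduced sizes are used in tests, stated
  below). Because the treated-arm posteriors factorize over mice when no
  parameter is shared, the constant-effect and cumulative models are
  sampled as independent per-mouse units in one batched run — this is
  mathematically identical to per-mouse fits and an order of magnitude
  faster. Joint runs are used whenever a parameter is shared ($K$, $\beta$).
  Burn-in is 25% of the chain by default; convergence is monitored by the
  integrated autocorrelation time with Sokal windowing, and chains failing
  the criterion (length $> 50\,\tau$) are extended automatically a bounded
  number of times, then flagged. The three-point-per-mouse design puts a
  long ridge in $(r, \alpha)$ — only net growth rates are strongly
  identified — so autocorrelation times are large and the flag is common at
  small chain lengths; summaries used by the package's tests were checked
  to be stable against chain doubling.

## Maximum likelihood and BIC

Model comparison uses $\mathrm{BIC} = Z \ln(n) - 2 \ln \hat L$ with $n$ the
total number of measurements in the arm and $Z$ the total number of sampled
parameters (mouse blocks, their $\sigma$'s, plus a shared $\beta$ where
present; the $\sigma$ convention is explicit so comparisons are
reproducible). By default $\ln \hat L$ is the maximum over retained
posterior draws — the sampled-posterior convention, with no optimizer.
An optional refinement (`mcmc_control(refine = TRUE)`) replaces it with a
bounded Levenberg-Marquardt maximization: $\sigma$ has the analytic profile
optimum $\max(1, \sqrt{SS/N_T})$, the remaining shape parameters are
optimized by least squares from several starts, and for shared-parameter
models the likelihood is profiled over the shared parameter. The refined
optimum is used by the tests that need the true ML point (for example the
noiseless-identifiability check); the default convention is used for BIC
comparisons. Note that with $\sigma$ free and exactly as many shape
parameters as measurements, the exact ML point is an interpolating fit with
$\sigma$ at its lower bound — a degenerate spike that the sampled-posterior
convention deliberately does not chase.

# Prior predictive checks

The prior predictive ensemble forward-simulates parameter draws from the
prior through the noiseless model on the measurement grid (no $\sigma$ draw
enters, matching the check's definition as a trajectory-plausibility
diagnostic). The coverage statistic is the percentage of observed points
inside the central 95% empirical interval at their measurement day;
quantiles use linear interpolation and points exactly on a bound count as
inside. High coverage indicates the priors generate dynamics at least as
dispersed as the data; the default number of draws is 10,000 (the check is
insensitive to this beyond a few thousand).

# Sensitivity analysis

Time-resolved total-effect Sobol indices are estimated with the Saltelli
design: uniform base matrices $A, B$ ($L \times Z$) and the $Z$
column-swapped hybrids $A_B^{(z)}$, requiring $L(Z+1)$ model evaluations
for the estimator

$$S_{T_z} \approx \frac{1}{2L} \sum_{j=1}^{L}
  \left( (Y_A)_j - (Y_{AB}^{(z)})_j \right)^2 .$$

This raw form is reported alongside the conventional variance-normalized
index (raw divided by the empirical variance of $Y$ over the $A$ and $B$
evaluations); the normalized form is the default for reporting because
"relative importance" across times is only meaningful on a common scale.
Plain Monte-Carlo uniform sampling is used; the default is $L = 4096$ with
a daily output grid over days 0-14. For comparisons between the
constant-effect and decaying-effect models, the decaying model's $\alpha$
is rescaled by $s = \beta \Delta t / (1 - e^{-\beta \Delta t})$ with
$\Delta t = 7$ d so both models deliver the same cumulative kill per dose
interval — without this, $\alpha$ means a different physical quantity in
the two models and their indices are incomparable. $s \to 1$ as
$\beta \to 0$ (a series expansion is used below $\beta\Delta t < 10^{-8}$)
and $s \ge 1$ always.

# Prediction schemes

Three schemes predict the day-14 volume, mimicking clinical forecasting:

1. **Mouse-specific**: fit $(r, \alpha, N_0, \sigma)$ to the mouse's day-0
   and day-7 data only, then propagate each posterior draw to day 14. The
   point prediction is the posterior median and the responder call compares
   it with the observed day-0 volume (strictly lower = responder; ties are
   non-responders).
2. **Leave-one-out**: fit the arm excluding the target mouse, draw 1000
   parameter sets uniformly from the pooled posterior (mouse block and
   iteration sampled uniformly — the output space of the estimation),
   start from the target's observed day-0 volume, and simulate days 7 and
   14. This scheme borrows population information but no individual signal.
3. **Group-informed**: fit $(r, \alpha_1, N_0, \sigma)$ to days 0-7 (only
   dose 1 is active there), then set $\alpha_2 = \alpha_1 / R$ per draw,
   where $R$ is the group's treatment resistivity — the ratio
   $\alpha_1/\alpha_2$ computed per posterior draw from a cumulative-model
   fit of the arm's mice, pooled, and summarized by the median (the mean is
   also reported; ratios use an $\alpha_2$ floor of $10^{-4}$ d$^{-1}$ to
   avoid blow-ups). By default $R$ is computed leaving the target mouse out
   of the pooled ratio, which keeps the prediction honest; a whole-group
   mode is available. With $R = 1$ the scheme reduces exactly to
   scheme 1.

Schemes 1 and 3 never see day-14 data; the fit object records the days
used, and the tests audit this.

# The synthetic cohort generator

Real cohorts of this design are rarely public, so the generator is a
first-class module: it emulates a six-arm study (control $n=8$, and five
treated arms of 18, 10, 9, 4 and 8 mice), enrollment volumes
$U(50, 150)$ mm$^3$, measurements at days 0/7/14, dose intervals starting
at days 0 and 7, and a sacrifice rule at 1000 mm$^3$ (measurements after
the first exceedance are removed; the triggering one is kept and flagged).
Per mouse, a responder status is drawn from the arm's responder fraction —
by default responders occur only in the first three treated arms, matching
the outcome pattern of the study design the generator emulates — and true
parameters are drawn from status-specific ranges: responders
$\alpha_1 \in [0.13, 0.3]$, $r \in [0.05, 0.15]$; non-responders
$\alpha_1 \in [0, 0.07]$, $r \in [0.15, 0.28]$; control
$r \in [0.05, 0.3]$. These ranges sit inside the inference prior box (so
recovery studies are identifiable, without prior-boundary pile-up) and are
separated enough that the drawn status almost always agrees with the
recorded truth label, which is always read off the noiseless trajectory
(day-14 strictly below day 0). A per-protocol resistivity $R$ sets
$\alpha_2 = \alpha_1/R$; $R = 1$ recovers the constant-effect model.
Noise is additive Gaussian per measurement, either a constant s.d.
(default 20 mm$^3$, a realistic scale for MRI-derived volumes in the
enrollment range) or proportional to the noiseless volume; noisy values are
floored at 1 mm$^3$ (noiseless values are returned exactly). The generator
emulates design, mixture structure and noise — it does not emulate
segmentation error structure, inter-measurement correlation, or model
misspecification, so passing recovery tests demonstrates correctness of
the machinery, not that real tumors follow the logistic-with-kill model.

For parameter-recovery and model-selection studies the generator is run
with a degenerate $K$ range equal to the value fixed in the fits: those
studies test the estimator on data from the fitted model, not robustness
to $K$ misspecification. The full-cohort default draws per-mouse
$K \in [800, 2000]$ mm$^3$.

# What the calibration studies show (and their sizes)

The package's acceptance-style tests run, on synthetic cohorts:

* **Prior-predictive coverage**: the control priors cover a synthetic
  control cohort (truths inside the prior box, noise 20 mm$^3$) at 100%.
* **Parameter recovery**: on a 20-mouse constant-effect arm with 5%
  proportional noise, 95% posterior intervals cover the true $r$ and
  $\alpha$ at a rate at least 0.85, and posterior-median $\alpha$ ranks
  every injected responder above every non-responder in at least 90% of
  pairs. Chains: 8 walkers per mouse, 1500 retained samples per walker,
  with automatic extension.
* **Model selection**: on arms generated from the constant-effect model,
  BIC prefers it over the decaying-effect model in at least 80% of 20
  replicates (4 mice per arm, 800 retained samples per walker).
* **Resistivity recovery**: an injected dose ratio $\alpha_1/\alpha_2 = 2$
  in an 18-mouse all-responder arm is recovered by the pooled posterior
  ratio median near the lower edge of $[1.5, 2.5]$. The attenuation toward
  1 is structural, not a sampling artifact: with symmetric $U(0, 0.3)$
  priors on both rates, three time points, and $\sigma$ free, the
  posterior ratio shrinks toward the prior's ratio median of 1. Longer
  chains move the estimate from $\approx 1.45$ (under-converged) to
  $\approx 1.5$ (converged) and no further.
* **Scheme ordering**: on cohorts with true dose-2 attenuation ($R = 2$),
  group-informed predictions achieve mean CCC at least that of
  mouse-specific predictions over 10 replicate arms — the qualitative
  ordering that motivates the hybrid scheme.

# Evaluation metrics and statistics

Agreement between observed and predicted volumes is summarized by Pearson
correlation, Lin's concordance correlation coefficient with population
($1/n$) moments (the original definition; sample moments change values
slightly and the convention is documented for that reason), and mean
absolute percent error. Responder accuracy is the fraction of correct
calls. Group comparisons use the two-tailed Mann-Whitney U test (exact for
small untied samples, normal approximation with tie correction otherwise)
with Bonferroni adjustment $\min(1, m p)$; within-group growth uses the
paired two-tailed t-test; inter-individual variability of posterior
parameters is summarized by a one-way random-effects ICC (mice as classes,
draws as repeated measures) and by the coefficient of variation of
per-mouse posterior medians (sample-s.d. convention). These delegate to
R's standard implementations where they exist.

# Known limitations

* With three measurements per mouse, $r$ and $\alpha$ are identified
  mainly through their difference; individual values lean on the prior
  bounds. This is intrinsic to the design, and it is why the control-arm
  posterior is used to tighten the treated-arm $r$ prior.
* The cumulative model's ratio estimator attenuates toward 1 under weak
  identifiability (see above); group resistivity estimates from short
  panels should be read as conservative.
* Fixing $K$ ignores its uncertainty; the joint control fit shows $K$ is
  itself weakly identified from 14-day windows, so treated-arm conclusions
  should not be sensitive to it, but this is an assumption, not a result.
* The leave-one-out scheme pools mouse blocks uniformly and therefore
  fails for atypical mice by construction; it is included as the
  population-information baseline.
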