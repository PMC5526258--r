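---
title: "Methods: simulating, breaking, and repairing a longitudinal exposure"
author: "longmisim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating, breaking, and repairing a longitudinal exposure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`longmisim` is a simulation laboratory for one sharply posed question: when
a continuous time-varying exposure with a *non-linear* trajectory over time
is incomplete, how well do the standard multiple-imputation (MI) methods —
fully conditional specification (FCS), multivariate normal imputation
(MVNI), and the two-fold FCS algorithm — recover the association between
that exposure and a repeated binary outcome, compared with a complete-case
analysis?  The package generates five-wave child-cohort panels, imposes
missingness, imputes, analyses, and scores the results, all behind a seeded
and paired replicate design.

## The data-generating model

Each simulated child has five time-invariant variables with a small causal
chain: maternal age feeds maternal education, education feeds (negatively)
maternal smoking, and child sex shifts birth weight.  The marginals are
configured as: sex ~ Bernoulli(0.49); maternal age ~ N(31, 5²) years
truncated to [18, 45]; birthweight ~ N(3.30 + 0.12·(1−sex), 0.55²) kg
truncated to [1, 6]; education ~ Bernoulli(expit(−0.6 + 0.05·(age−31)));
smoking ~ Bernoulli(expit(−1.0 − 0.9·education)).  These are plausible
values for an Australian birth cohort and are configuration, not estimates;
any downstream quantity that depends on them (notably the magnitude of
complete-case bias under MAR) should be read as *structurally*, not
numerically, comparable to published cohort analyses.

Ages at the five waves start at N(57, 3²) months (truncated to [48, 72])
and advance by 24 + N(0, 1) months per wave, i.e. biennial data collection
from about age 4¾ to about age 13.

The binary outcome (sleep problems) at wave 1 follows a logistic model on
education, sex, birth weight and maternal age.  The exposure — a BMI-for-age
z-score, `bmiz` — follows a linear mixed model, quadratic in age:

bmiz_ij = (θ₀+a₀ᵢ) + θ₁·sleep₁ᵢ + (θ₂+a₁ᵢ)·age_ij + (θ₃+a₂ᵢ)·age²_ij +
θ₄·edu + θ₅·smoke + θ₆·sex + θ₇·bw + θ₈·mage + ε_ij,

with (a₀,a₁,a₂) ~ MVN(0, Σ) per child and ε ~ N(0, σ²).  Defaults:
θ₁ = 0.10, θ₂ = 0.015/month, θ₃ = −5×10⁻⁵/month², θ₄ = −0.10, θ₅ = 0.15,
θ₆ = −0.05, θ₇ = 0.40, θ₈ = −0.005, σ = 0.45; random-effect SDs
(0.85, 0.004, 10⁻⁵) with corr(a₀,a₁) = −0.3.  The negative θ₃ makes the
trajectory concave over the observed age range — the non-linearity whose
imputation behaviour is the whole point of the study.

Sleep problems at waves 2–5 are then generated sequentially from the
*lagged* exposure:

logit P(sleep_j = 1) = λ₀ + λ₁·bmiz_{j−1} + λ₂·edu + λ₃·sex + λ₄·bw +
λ₅·mage + λ₆·sleep_{j−1},

with λ₂ = −0.20, λ₃ = 0.10, λ₄ = −0.10, λ₅ = −0.01, λ₆ = 1.2.  λ₁ is the
estimand; the two scenarios store it as exactly log(1.1) and log(1.5), not
the rounded 0.1/0.4.  Because the analysis model below has exactly this
form, λ₁ is the true value of the analysis parameter ("congeniality by
construction").

### Intercept calibration

The three intercepts are not free parameters: they are solved for so that
(i) wave-1 sleep-problem prevalence is 0.15, (ii) mean wave-1 bmiz is 0.30,
and (iii) sleep-problem prevalence averaged over waves 2–5 is 0.15 under
the scenario's λ₁.  `calibrate_dgm_params()` does this with a Monte Carlo
calibration cohort of 100 000 children on a dedicated fixed random stream
(so the intercepts are reproducible constants): η₀ by monotone root-finding
of the mean of expit over the cohort, θ₀ in closed form from the
fixed-effect mean, and λ₀ by root-finding on the *exactly* forward-
propagated prevalence of the sleep chain given the cohort's realised bmiz
draws (the lagged outcome is marginalised analytically wave by wave, so the
objective is smooth and `uniroot` converges to 10⁻⁹).

A design choice worth recording: λ₀ is a single scalar targeting the
*average* prevalence over waves 2–5, not a wave-specific intercept vector.
A per-wave intercept would pin every wave's prevalence at exactly 0.15 but
would break the congeniality between the generating model and the
single-intercept analysis model, turning the estimand into a moving
target.  With the scalar intercept the per-wave prevalences drift by less
than 0.01 across waves (measured 0.147–0.156 at n = 100 000), which we
accept.

## Imposing missingness

Only `bmiz` at waves 2–5 is ever made missing; wave-1 bmiz, all sleep
indicators and all covariates stay complete.  Cumulative missingness rises
linearly to its final level (25% or 50%) at wave 5: the target at wave j is
`final·(j−1)/4`.  Each wave's new missingness is split half-and-half
between two patterns:

* **Model A (dropout)**: once drawn, bmiz is missing at every later wave;
* **Model B (intermittent)**: missing at that wave only, drawn among
  children not already dropped out.

Under MAR both models are logistic in sleep problems at wave 1, sleep
problems at wave 5, and maternal smoking, with odds ratios (weak scenario)
1.67/1.64/1.61 for model A and 1.61/1.58/1.58 for model B; the strong
scenario doubles the log odds ratios (squares the ORs).  Under MCAR the
same machinery runs with all slopes zero, so the two mechanisms share
every structural property except the dependence on data.  The wave- and
dataset-specific intercepts are found by `calibrate_intercept()` — monotone
root-finding on the expected proportion given the realised covariates, to
10⁻⁶ — so the *expected* missing fraction hits its target in every
replicate; realised fractions differ only by binomial noise.

Missingness depends on the wave-5 *outcome* and on maternal smoking (which
affects the outcome only through bmiz), which is what makes the
complete-case analysis biased under MAR while leaving MI, which sees those
variables, recoverable.

## The three imputation engines

All engines treat each wave's bmiz as a distinct variable and use the
auxiliary maternal smoking; since only four continuous variables are ever
incomplete, every univariate model is a Bayesian normal linear regression
and no logistic imputation is needed.

* **FCS** (`fcs_impute`): holes initialised from observed margins, then 10
  cycles over bmiz₂…bmiz₅, each drawn from the posterior predictive of a
  normal linear model on bmiz at all other waves, sleep at all waves, and
  the five time-invariant variables ("just another variable").
* **MVNI** (`mvni_impute`): one joint multivariate normal over all fifteen
  variables, fitted by data augmentation — I-step draws each missingness
  pattern's block from its conditional normal; P-step draws (μ, Σ) from the
  normal–inverse-Wishart posterior under the Jeffreys prior.  Defaults: 200
  burn-in iterations and 100 between saved imputations.  Binary variables
  enter the normal model but are never imputed, so the normality assumption
  on them is inert.
* **Two-fold FCS** (`twofold_fcs_impute`): like FCS, but bmiz at time t is
  imputed using only the time block {t−w, …, t+w} ∩ [1,5] of bmiz and sleep
  (plus all time-invariant variables), sweeping the time points in order
  for 10 among-time iterations with 1 within-time cycle.  Width w = 1 is
  the standard algorithm; w = 2 widens the window; w = 4 makes the
  predictor set identical to FCS at every t, which the test suite uses as
  an equivalence check.

The posterior-predictive draw itself (σ*² from the scaled inverse-χ²,
β* from N(β̂, σ*²(XᵀX)⁻¹), then y* = Xβ* + σ*z) is exposed as
`bayesian_linear_draw()`; a 10⁻⁸ trace-scaled ridge guards near-singular
cross-products and genuinely collinear designs raise an error naming the
offending columns.  Default m = 50 imputations; every imputation runs in
its own derived substream so results cannot depend on execution order.

Iteration counts (10 FCS cycles, 200/100 DA burn-in/thinning, 10 among-
iterations) are conventional choices — the methods being emulated do not
prescribe them — and are all configurable in `imputation_config()`.

## Target analysis and pooling

The substantive model is a marginal logistic regression of sleep problems
at waves 2–5 on lagged bmiz, education, sex, birth weight, maternal age and
the lagged outcome, fitted by GEE with an unstructured 4×4 working
correlation and robust sandwich standard errors (`fit_gee`).  Because
every analysed child contributes all four waves (MI completes the panel;
the complete-case rule drops whole children), clusters are balanced and
the fitter exploits that.  Numerical choices: Fisher scoring with the
working correlation re-estimated from Pearson residuals each step until
the coefficient update falls below 10⁻³, after which the correlation is
frozen so the Newton tail converges quadratically; convergence at max
|Δβ| < 10⁻⁶ (verified to reproduce a 10⁻⁸ fit to seven significant
digits); a non-positive-definite unstructured estimate falls back to
exchangeable for that dataset and is flagged.  The implementation is
validated against ordinary logistic regression with cluster-robust
standard errors in the independence limit (agreement ~10⁻⁶) and against an
independent external GEE implementation for the unstructured structure
(coefficients to ~10⁻³ at n = 800; the residual difference is the two
packages' moment-estimator denominators).

The complete-case rule drops children with any missing bmiz at waves 2–4;
wave-5 bmiz never enters the analysis (the wave-5 row uses bmiz₄), so
missingness there is irrelevant to inclusion.

MI estimates are pooled by Rubin's rules (`rubin_pool`): mean estimate,
within-variance W = mean(se²), between-variance B, total T = W + (1+1/m)B,
with Rubin's classic (1987) degrees of freedom (m−1)(1 + W/((1+1/m)B))².
At n = 5000 the Barnard–Rubin small-sample correction would change
intervals negligibly, so the classic form is used; B = 0 falls back to the
normal interval.

## Performance measures

`summarize_performance()` reports, per scenario × method cell: absolute
bias |mean(est) − λ₁| (signed bias is kept internally), relative bias as a
percentage of λ₁, empirical SE (SD of estimates), model-based SE (mean of
estimated SEs), 95% CI coverage, RMSE defined as √(bias² + empSE²) — the
definition that reproduces the published arithmetic, differing from
√mean((est−λ₁)²) only by the variance denominator convention — and the
Monte Carlo error empSE/√R.

## Scale, seeds, and what the tests do and do not show

The full design — 1000 replicates of 5000 children, m = 50, all 60
scenario × method cells — is a cluster-afternoon job.  The package runs it
through the same `run_scenario()`/`run_study()` code path at any scale;
the bundled checks use desk scales chosen once: the test suite runs 60
replicates of n = 2500 with m = 5 per cell, and `scripts/acceptance.R`
runs 80 replicates of n = 5000 with m = 10.  At these scales the Monte
Carlo allowances (2·empSE/√R for biases, binomial ±3·√(200/R) points for
coverages) are computed from the runs themselves and reported alongside.
Replicate seeds derive from (master seed, canonical scenario index,
replicate index), so every method sees the identical incomplete dataset —
method comparisons are paired — and enabling or disabling methods never
changes another method's results.

The generator emulates the *structure* of a real cohort (dependency chain
among covariates, quadratic exposure trajectory with person-level random
effects, lagged outcome feedback, realistic prevalences and missingness
proportions), not any cohort's fitted coefficients, which are not publicly
available.  Consequently: near-unbiasedness of MI, nominal coverage,
Rubin/RMSE arithmetic and the qualitative ordering "complete-case bias ≫
MI bias under strong MAR at 50%" are reproducible, sharply testable
claims; the numerical size of the complete-case degradation (here:
relative bias ≈ 36%, coverage ≈ 80% in the pilot at 50% strong MAR) tracks
the published pattern qualitatively but not cell by cell.  Other known
limitations: binary variables are never imputed (holes are confined to the
continuous exposure by design, so no engine here exercises logistic
imputation); ages are excluded from the imputation models (they are
near-deterministic and absent from the emulated predictor set); and the
working-correlation moment estimator assumes the balanced four-wave
layout that the pipelines guarantee.

## Compiled kernels

The three inner loops — GEE scoring, the chained-equation draw cycle, and
the data-augmentation chain — run in C++ (RcppArmadillo), drawing all
randomness from R's RNG so `set.seed()` semantics are identical to the
pure-R primitives they mirror; `bayesian_linear_draw()` and the R-level
wrappers remain the reference implementations for the oracle tests.
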