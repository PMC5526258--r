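# longmisim

Missing data are endemic in longitudinal cohort studies, and the exposure
you care about is often the thing that goes missing. `longmisim` is an R
package for studying — by simulation — how well the standard
multiple-imputation (MI) methods handle a **continuous time-varying
exposure with a non-linear trajectory over time**, compared with a
complete-case analysis. It is aimed at biostatisticians and
epidemiologists who want a reproducible, end-to-end harness for this
setting rather than one-off simulation scripts.

The emulated setting is a five-wave child cohort: BMI-for-age z-scores
(`bmiz`, the exposure) follow a quadratic-in-age linear mixed model with
person-level random intercept and slopes, and a repeated binary outcome
(sleep problems) depends on the *lagged* exposure,

```
logit P(sleep_j = 1) = λ0 + λ1·bmiz_{j−1} + λ2·edu + λ3·sex
                     + λ4·bw + λ5·mage + λ6·sleep_{j−1},   j = 2,…,5
```

so the estimand is the exposure log odds ratio λ1 (simulated at log 1.1
and log 1.5). Missingness is imposed on `bmiz` at waves 2–5 only — MCAR,
or MAR through logistic models on wave-1 sleep, wave-5 sleep and maternal
smoking, mixing monotone dropout with intermittent gaps, with intercepts
calibrated by root-finding to hit 25% or 50% cumulative missingness at
wave 5. Five estimators are compared:

| method | idea |
|---|---|
| `CCA` | drop children with any missing bmiz at waves 2–4 |
| `FCS` | chained equations, each wave a distinct variable |
| `MVNI` | joint multivariate normal fitted by data augmentation |
| `TWOFOLD_W1` | two-fold FCS, predictors restricted to adjacent waves |
| `TWOFOLD_W2` | two-fold FCS with a time-window width of 2 |

The target analysis is a GEE logistic regression (unstructured working
correlation, robust SEs) of the outcome on the lagged exposure, written
in-package and validated against `glm` + cluster-robust sandwich SEs and
an external GEE implementation. MI estimates are pooled by Rubin's rules;
each scenario × method cell is scored by absolute and relative bias,
empirical and model-based SE, 95% coverage, RMSE = √(bias² + empSE²), and
Monte Carlo error. The inner loops (GEE scoring, chained draws, the
data-augmentation chain) run in compiled RcppArmadillo kernels using R's
RNG, so everything is seed-reproducible.

## A worked example

```r
library(longmisim)

dgm   <- default_dgm_params(true_or = 1.1)   # intercepts auto-calibrated
panel <- generate_cohort(5000, dgm, seed = 42)
pat   <- apply_missingness(panel,
                           missingness_spec("MAR_strong", target_final = 0.5),
                           seed = 7)
sapply(2:5, missing_fraction, pattern = pat)
#> [1] 0.1312 0.2518 0.3780 0.5008       # linear ramp to 50% at wave 5

cca <- complete_case_estimate(pat)
c(cca$beta1, cca$se)
#> [1] 0.04205544 0.02944452              # truth is log(1.1) = 0.0953

fcs <- fcs_impute(pat, imputation_config(m = 10), seed = 3)
pooled <- pooled_gee_estimate(fcs)
c(pooled$estimate, pooled$se)
#> [1] 0.09613048 0.02254775              # MI recovers the association
```

On this replicate the complete-case estimate collapses towards zero
(children missing mid-study bmiz are dropped, and missingness depends on
the outcome), while FCS with 10 imputations lands on the true log odds
ratio with a properly inflated standard error. A replicated scenario runs
through one call:

```r
cfg <- study_config(n_individuals = 5000, n_replicates = 20, true_ors = 1.1,
                    mechanisms = "MAR_strong", proportions = 0.5,
                    methods = c("CCA", "FCS", "MVNI", "TWOFOLD_W1"),
                    imputation = imputation_config(m = 10), master_seed = 99)
run <- run_scenario(cfg, "MAR_strong", 0.5, 1.1)
run$summaries[, c("method", "absolute_bias", "relative_bias_pct", "coverage_pct")]
#>       method absolute_bias relative_bias_pct coverage_pct
#> 1        CCA      0.034166            35.847           80
#> 2        FCS      0.001028             1.079          100
#> 3       MVNI      0.000408             0.428          100
#> 4 TWOFOLD_W1      0.003816             4.004          100
```

`run_study()` iterates the full mechanism × proportion × odds-ratio grid
(the complete design is 60 cells), `write_results()` emits tidy CSVs plus
a JSON manifest, and `inst/cli/longmisim` exposes `simulate`, `impose`,
`impute`, `analyze` and `study` subcommands for shell use. Replicate seeds
are paired: every method sees the identical incomplete datasets.

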