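test_that("the long analysis table implements the lag structure", {
  panel <- small_cohort(250)
  long <- build_analysis_long(panel)
  expect_equal(nrow(long), 4 * 250)
  one <- long[long$id == panel$id[1], ]
  expect_equal(nrow(one), 4)
  expect_equal(one$wave, 2:5)
  # wave-2 row carries the wave-1 exposure and lagged outcome
  expect_equal(one$bmiz_prev[1], panel$bmiz1[1])
  expect_equal(one$sleep_prev[1], panel$sleep_prob1[1])
  expect_equal(one$y[1], panel$sleep_prob2[1])
  # bmiz5 never enters
  expect_equal(long$bmiz_prev[long$wave == 5], panel$bmiz4)
  expect_error(build_analysis_long(panel[, -match("bmiz2", names(panel))]),
               "lacks columns")
})

test_that("GEE matches ordinary logistic regression with cluster-robust SEs in the independence limit", {
  panel <- small_cohort(800, seed = 11)
  long <- build_analysis_long(panel)
  f <- fit_gee(long, corstr = "independence")
  g <- glm(y ~ bmiz_prev + m_education + sex + birthweight + m_age +
             sleep_prev, binomial, data = long)
  expect_lt(abs(f$beta1 - coef(g)[["bmiz_prev"]]), 1e-3)
  V <- sandwich::vcovCL(g, cluster = long$id, type = "HC0", cadjust = FALSE)
  expect_equal(f$se, sqrt(V["bmiz_prev", "bmiz_prev"]), tolerance = 1e-4)
})

test_that("GEE with unstructured correlation agrees with an external implementation", {
  # statsmodels (Python) as an independent oracle on the same dataset;
  # small convention differences in the moment estimator of the working
  # correlation leave the coefficients equal to ~1e-3
  panel <- small_cohort(800, seed = 11)
  long <- build_analysis_long(panel)
  f <- fit_gee(long, corstr = "unstructured")
  csv <- tempfile(fileext = ".csv")
  out <- tempfile(fileext = ".txt")
  write.csv(long, csv, row.names = FALSE)
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys, pandas as pd, statsmodels.api as sm",
    sprintf("d = pd.read_csv('%s')", csv),
    "X = sm.add_constant(d[['bmiz_prev','m_education','sex','birthweight','m_age','sleep_prev']])",
    "m = sm.GEE(d['y'], X, groups=d['id'], family=sm.families.Binomial(),",
    "           cov_struct=sm.cov_struct.Unstructured(), time=(d['wave']-2).values)",
    "r = m.fit(maxiter=200)",
    sprintf("open('%s','w').write('%%.10f %%.10f' %% (r.params['bmiz_prev'], r.bse['bmiz_prev']))", out)
  ), script)
  status <- suppressWarnings(system2("python", script, stdout = FALSE,
                                     stderr = FALSE))
  expect_equal(status, 0L)
  ref <- scan(out, quiet = TRUE)
  expect_lt(abs(f$beta1 - ref[1]), 2e-3)
  expect_lt(abs(f$se / ref[2] - 1), 0.01)
})

test_that("GEE recovers a null exposure effect", {
  # generated with lambda1 = 0 and no random effects
  null_dgm <- memo("null_dgm", function() {
    p <- dgm_params(bmiz = bmiz_params(Sigma_a = diag(0, 3)),
                    followup = sleep_followup_params(lambda1 = 0))
    calibrate_dgm_params(p, n_calib = 5e4)
  })
  panel <- generate_cohort(50000, null_dgm, seed = 17)
  f <- fit_gee(build_analysis_long(panel))
  expect_true(f$converged)
  expect_lt(abs(f$beta1), 2 * f$se)
  expect_true(f$ci_low < f$beta1 && f$beta1 < f$ci_high)
})

test_that("complete-case rule drops exactly the children missing bmiz at waves 2-4", {
  panel <- small_cohort(600, seed = 23)
  # child 1 missing only bmiz5: retained; child 2 missing bmiz3: dropped
  masked <- mask_cells(panel, c(1, 2), c(5, 3))
  fit <- complete_case_estimate(masked)
  expect_equal(fit$n_clusters, 599)
  # zero missingness reproduces the full-data fit exactly
  f_full <- fit_gee(build_analysis_long(panel))
  f_cc <- complete_case_estimate(panel)
  expect_equal(f_cc$beta1, f_full$beta1)
  expect_equal(f_cc$se, f_full$se)
})

test_that("Rubin pooling reproduces its defining arithmetic", {
  # hand-evaluated example
  pool <- rubin_pool(c(0.10, 0.12, 0.14), ses = rep(0.02, 3))
  expect_equal(pool$estimate, 0.12)
  expect_equal(pool$W, 4e-4)
  expect_equal(pool$B, 4e-4)
  expect_equal(pool$T, 4e-4 + (1 + 1 / 3) * 4e-4)
  expect_equal(pool$T, 9.333e-4, tolerance = 1e-4)
  expect_equal(pool$se, 0.03055, tolerance = 1e-4)
  expect_equal(pool$df, 2 * (1 + 4e-4 / ((4 / 3) * 4e-4))^2)

  # degenerate pooling: identical estimates give B = 0 and the
  # per-imputation standard error back
  p0 <- rubin_pool(rep(0.1, 5), ses = rep(0.02, 5))
  expect_equal(p0$estimate, 0.1)
  expect_equal(p0$se, 0.02)
  expect_equal(p0$df, Inf)

  expect_error(rubin_pool(0.1, ses = 0.02), "at least 2")

  # pooled se is never below the within-imputation component
  set.seed(8)
  for (k in 1:20) {
    est <- rnorm(5, 0.1, 0.03)
    ses <- runif(5, 0.01, 0.05)
    p <- rubin_pool(est, ses = ses)
    expect_gte(p$se, sqrt(p$W))
  }
})

test_that("pooled intervals widen relative to single fits when imputations disagree", {
  pat <- small_pattern(800, mechanism = "MCAR", prop = 0.5)
  cs <- fcs_impute(pat, imputation_config(m = 5), seed = 2)
  pooled <- pooled_gee_estimate(cs)
  expect_gt(pooled$B, 0)
  one <- fit_gee(build_analysis_long(cs$panels[[1]]))
  expect_gt(pooled$ci_high - pooled$ci_low, one$ci_high - one$ci_low)
})
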