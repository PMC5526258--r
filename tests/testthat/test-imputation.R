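test_that("bayesian_linear_draw is a proper posterior-predictive draw", {
  expect_identical(bayesian_linear_draw(rnorm(10), matrix(1, 10),
                                        matrix(1, 0, 1)), numeric(0))

  # noiseless limit: y exactly linear in X => draws approach the fit
  n <- 5000
  x <- seq_len(n) / n
  X <- cbind(1, x)
  y <- 2 + 3 * x
  imp <- bayesian_linear_draw(y, X, cbind(1, c(0.25, 0.75)), seed = 1)
  expect_equal(imp, 2 + 3 * c(0.25, 0.75), tolerance = 1e-4)

  # 20-row toy: between-draw variance matches the analytic posterior
  # predictive variance sigma2 * (1 + h) * df/(df-2) under the
  # noninformative prior
  set.seed(99)
  Xo <- cbind(1, rnorm(20))
  yo <- 1 + 0.5 * Xo[, 2] + rnorm(20, 0, 0.7)
  Xm <- cbind(1, 0.3)
  draws <- vapply(1:4000, function(k) {
    bayesian_linear_draw(yo, Xo, Xm, seed = 1e6 + k)
  }, numeric(1))
  bh <- qr.solve(Xo, yo)
  s2 <- sum((yo - Xo %*% bh)^2) / 18
  h <- drop(Xm %*% chol2inv(chol(crossprod(Xo))) %*% t(Xm))
  v_oracle <- s2 * (1 + h) * 18 / 16  # t-scale inflation, df = n - p = 18
  expect_equal(mean(draws), drop(Xm %*% bh), tolerance = 0.05)
  expect_equal(var(draws), v_oracle, tolerance = 0.12 * v_oracle)

  # collinear design errors out naming the problem
  Xbad <- cbind(a = rep(1, 30), b = 1:30, c = 2 * (1:30))
  expect_error(bayesian_linear_draw(rnorm(30), Xbad, Xbad[1:2, ]),
               "degenerate|collinear")
})

test_that("a hole-free panel passes through every engine untouched", {
  panel <- small_cohort(300)
  cfg <- imputation_config(m = 3, da_burnin = 5, da_thin = 2)
  for (fn in list(fcs_impute, mvni_impute, twofold_fcs_impute)) {
    cs <- fn(panel, cfg, seed = 4)
    expect_length(cs$panels, 3)
    for (k in 1:3) {
      expect_equal(as.matrix(cs$panels[[k]][paste0("bmiz", 1:5)]),
                   as.matrix(panel[paste0("bmiz", 1:5)]),
                   ignore_attr = TRUE)
    }
  }
})

test_that("the study default is 50 imputations", {
  expect_equal(imputation_config()$m, 50L)
  expect_error(imputation_config(m = 1), "m must be")
})

test_that("observed cells are preserved and imputations are proper", {
  pat <- small_pattern(1000, mechanism = "MCAR", prop = 0.5)
  obs <- !is.na(as.matrix(pat$panel[paste0("bmiz", 1:5)]))
  truth <- as.matrix(pat$panel[paste0("bmiz", 1:5)])
  cfg <- imputation_config(m = 4, da_burnin = 30, da_thin = 5)
  for (fn in list(fcs_impute, mvni_impute, twofold_fcs_impute)) {
    cs <- fn(pat, cfg, seed = 21)
    imp <- lapply(cs$panels, function(p) {
      as.matrix(p[paste0("bmiz", 1:5)])
    })
    for (k in seq_along(imp)) {
      expect_identical(imp[[k]][obs], truth[obs])
      expect_false(anyNA(imp[[k]]))
    }
    # properness: imputed cells vary across imputations
    hole1 <- which(!obs[, 2])[1]
    vals <- vapply(imp, function(M) M[hole1, 2], numeric(1))
    expect_gt(var(vals), 0)
  }
})

test_that("imputed values recover the masked truth on average (MCAR mask-and-recover)", {
  panel <- memo("cohort_5k", function() generate_cohort(5000, default_dgm(),
                                                        seed = 3030))
  pat <- apply_mcar(panel, missingness_spec("MCAR", 0.25), seed = 31)
  masked_cells <- is.na(as.matrix(pat$panel[paste0("bmiz", 2:5)]))
  true_vals <- as.matrix(panel[paste0("bmiz", 2:5)])[masked_cells]
  cfg <- imputation_config(m = 5, da_burnin = 50, da_thin = 10)
  for (fn in list(fcs_impute, mvni_impute, twofold_fcs_impute)) {
    cs <- fn(pat, cfg, seed = 77)
    imp_mean <- rowMeans(vapply(cs$panels, function(p) {
      as.matrix(p[paste0("bmiz", 2:5)])[masked_cells]
    }, numeric(sum(masked_cells))))
    expect_lt(abs(mean(imp_mean) - mean(true_vals)), 0.05)
  }
})

test_that("data augmentation recovers a known bivariate correlation", {
  set.seed(314)
  n <- 2000
  x <- rnorm(n)
  y <- 0.6 * x + sqrt(1 - 0.36) * rnorm(n)
  Y <- cbind(x, y)
  Y[sample(n, 600), 2] <- NA  # 30% MCAR on the second variable
  imps <- mvn_da_impute(Y, m = 10, burnin = 50, thin = 10, seed = 9)
  rho <- mean(vapply(imps, function(M) cor(M[, 1], M[, 2]), numeric(1)))
  expect_lt(abs(rho - 0.6), 0.05)
})

test_that("FCS uses the just-another-variable predictor set", {
  pat <- small_pattern(500)
  cs <- fcs_impute(pat, imputation_config(m = 2), seed = 1)
  for (t in 2:5) {
    pd <- cs$predictors[[paste0("bmiz", t)]]
    expect_setequal(pd, c(paste0("bmiz", setdiff(1:5, t)),
                          paste0("sleep_prob", 1:5),
                          "m_education", "sex", "birthweight", "m_age",
                          "m_smoking"))
  }
})

test_that("two-fold windows truncate at the panel boundary and respect the width", {
  expect_equal(twofold_window(3, 1), 2:4)
  expect_equal(twofold_window(5, 1), 4:5)
  expect_equal(twofold_window(3, 2), 1:5)
  pat <- small_pattern(500)
  for (w in 1:2) {
    cfg <- imputation_config(m = 2, window_width = w)
    cs <- twofold_fcs_impute(pat, cfg, seed = 1)
    for (t in 2:5) {
      pd <- cs$predictors[[paste0("bmiz", t)]]
      waves_used <- as.integer(gsub("\\D", "", grep("^bmiz|^sleep_prob",
                                                    pd, value = TRUE)))
      expect_true(all(abs(waves_used - t) <= w))
      expect_true(all(c("m_education", "sex", "birthweight", "m_age",
                        "m_smoking") %in% pd))
    }
  }
})

test_that("a width-4 window makes two-fold FCS equivalent to standard FCS", {
  panel <- memo("cohort_2k_eq", function() generate_cohort(2000,
                                                           default_dgm(),
                                                           seed = 555))
  pat <- apply_mcar(panel, missingness_spec("MCAR", 0.25), seed = 556)
  m <- 20
  cs_f <- fcs_impute(pat, imputation_config(m = m), seed = 60)
  cs_t <- twofold_fcs_impute(pat, imputation_config(m = m, window_width = 4),
                             seed = 61)
  # identical predictor sets at every time point
  for (t in 2:5) {
    expect_setequal(cs_t$predictors[[paste0("bmiz", t)]],
                    cs_f$predictors[[paste0("bmiz", t)]])
  }
  pf <- pooled_gee_estimate(cs_f)
  pt <- pooled_gee_estimate(cs_t)
  tol <- 4 * sqrt(pf$B / m + pt$B / m)  # between-imputation MC allowance
  expect_lt(abs(pf$estimate - pt$estimate), tol)
})
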