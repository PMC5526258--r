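test_that("time-invariant profiles are reproducible and match configured marginals", {
  p1 <- sample_time_invariant(4, seed = 99)
  p2 <- sample_time_invariant(4, seed = 99)
  expect_identical(p1, p2)
  expect_error(sample_time_invariant(0, seed = 1), "n must be")

  big <- sample_time_invariant(1e5, seed = 123)
  expect_lt(abs(mean(big$sex) - 0.49), 0.01)
  expect_true(all(big$birthweight > 0))
  expect_true(all(big$m_age >= 15 & big$m_age <= 50))
  expect_true(all(big$m_education %in% 0:1 & big$m_smoking %in% 0:1))
  # education rises with maternal age; smoking falls with education
  expect_gt(cor(big$m_education, big$m_age), 0)
  expect_lt(cor(big$m_smoking, big$m_education), 0)
})

test_that("wave-1 sleep model saturates and hits its calibrated prevalence", {
  prof <- sample_time_invariant(2000, seed = 5)
  flat <- wave1_sleep_params(eta0 = 0, eta1 = 0, eta2 = 0, eta3 = 0, eta4 = 0)
  s <- sample_wave1_sleep(prof, flat, seed = 1)
  expect_lt(abs(mean(s) - 0.5), 0.05)  # expit(0) = 0.5 exactly
  sat <- wave1_sleep_params(eta0 = -1e6, eta1 = 0, eta2 = 0, eta3 = 0,
                            eta4 = 0)
  expect_true(all(sample_wave1_sleep(prof, sat, seed = 1) == 0))

  dgm <- default_dgm()
  big <- sample_time_invariant(1e5, seed = 123)
  s <- sample_wave1_sleep(big, dgm$wave1_sleep, seed = 77)
  expect_lt(abs(mean(s) - 0.15), 0.01)
})

test_that("bmiz trajectories degenerate correctly without noise", {
  n <- 6
  prof <- sample_time_invariant(n, seed = 3)
  prof[] <- lapply(prof, function(x) rep(x[1], n))  # identical covariates
  ages <- matrix(rep(c(57, 81, 105, 129, 153), each = n), n, 5)
  p0 <- bmiz_params(theta0 = 0.3, sigma_eps = 1e-12, Sigma_a = diag(0, 3))
  b <- sample_bmiz_trajectory(prof, rep(1, n), ages, p0, seed = 9)
  expect_equal(max(abs(sweep(b, 2, b[1, ]))), 0, tolerance = 1e-8)

  # with Sigma_a = 0 the residual variance at fixed covariates is sigma_eps^2
  p1 <- bmiz_params(theta0 = 0.3, sigma_eps = 0.45, Sigma_a = diag(0, 3))
  nn <- 20000
  prof2 <- prof[rep(1, nn), ]
  ages2 <- ages[rep(1, nn), ]
  b2 <- sample_bmiz_trajectory(prof2, rep(1, nn), ages2, p1, seed = 10)
  expect_lt(abs(sd(b2[, 3]) - 0.45), 0.01)

  expect_error(bmiz_params(Sigma_a = matrix(c(1, 2, 0, 2, 1, 0, 0, 0, 1), 3)),
               "positive semi-definite")
})

test_that("least squares on the generating design recovers the trajectory fixed effects", {
  dgm <- default_dgm()
  n <- 50000
  panel <- memo("big_cohort_50k", function() generate_cohort(n, dgm, seed = 202))
  bp <- dgm$bmiz
  y <- unlist(panel[paste0("bmiz", 1:5)], use.names = FALSE)
  X <- cbind(1,
             sleep1 = rep(panel$sleep_prob1, 5),
             scage = unlist(panel[paste0("scage", 1:5)], use.names = FALSE),
             scage_sq = unlist(panel[paste0("scage_sq", 1:5)],
                               use.names = FALSE),
             m_education = rep(panel$m_education, 5),
             m_smoking = rep(panel$m_smoking, 5),
             sex = rep(panel$sex, 5),
             birthweight = rep(panel$birthweight, 5),
             m_age = rep(panel$m_age, 5))
  fit <- lm.fit(X, y)
  theta_hat <- fit$coefficients
  theta_true <- unlist(bp[c("theta0", "theta1", "theta2", "theta3", "theta4",
                            "theta5", "theta6", "theta7", "theta8")])
  # cluster-robust (CR0) covariance: OLS is unbiased but errors are
  # correlated within children through the random effects
  Xr <- X * fit$residuals
  cl <- rep(seq_len(n), 5)
  G <- rowsum(Xr, cl)
  XtXi <- chol2inv(chol(crossprod(X)))
  Vcl <- XtXi %*% crossprod(G) %*% XtXi
  z <- (theta_hat - theta_true) / sqrt(diag(Vcl))
  # joint Wald test over the 9 coefficients plus a generous per-coefficient
  # bound (9 simultaneous comparisons)
  stat <- drop(crossprod(theta_hat - theta_true,
                         solve(Vcl, theta_hat - theta_true)))
  expect_lt(stat, qchisq(0.999, df = 9))
  expect_true(all(abs(z) < 3.3))
})

test_that("quadratic age term leaves a linear-in-age fit strictly worse", {
  panel <- small_cohort(2000, seed = 31)
  y <- unlist(panel[paste0("bmiz", 1:5)], use.names = FALSE)
  age <- unlist(panel[paste0("scage", 1:5)], use.names = FALSE)
  rss_lin <- sum(lm.fit(cbind(1, age), y)$residuals^2)
  rss_quad <- sum(lm.fit(cbind(1, age, age^2), y)$residuals^2)
  expect_lt(rss_quad, rss_lin * 0.999)
})

test_that("follow-up sleep problems hit their calibrated prevalence and null model is null", {
  dgm <- default_dgm()
  panel <- memo("cohort_1e5", function() generate_cohort(1e5, dgm, seed = 404))
  prev <- vapply(2:5, function(j) mean(panel[[paste0("sleep_prob", j)]]),
                 numeric(1))
  expect_true(all(abs(prev - 0.15) < 0.01))
  expect_lt(abs(mean(prev) - 0.15), 0.005)

  # exposure-null model: lambda1 = 0 and no other dependence => outcome
  # independent of bmiz
  null_p <- sleep_followup_params(lambda0 = qlogis(0.3), lambda1 = 0,
                                  lambda2 = 0, lambda3 = 0, lambda4 = 0,
                                  lambda5 = 0, lambda6 = 0)
  sub <- panel[1:50000, ]
  s <- sample_sleep_followup(sub, null_p, seed = 5)
  or <- function(y, x) {
    hi <- x > stats::median(x)
    (mean(y[hi]) / (1 - mean(y[hi]))) / (mean(y[!hi]) / (1 - mean(y[!hi])))
  }
  expect_lt(abs(or(s[, 1], sub$bmiz1) - 1), 0.06)
})

test_that("generate_cohort is complete, deterministic, and internally consistent", {
  p1 <- generate_cohort(500, default_dgm(), seed = 88)
  p2 <- generate_cohort(500, default_dgm(), seed = 88)
  expect_identical(p1, p2)
  expect_equal(nrow(p1), 500)
  expect_false(anyNA(p1))
  for (j in 1:5) {
    expect_equal(p1[[paste0("scage_sq", j)]], p1[[paste0("scage", j)]]^2)
  }
  ages <- as.matrix(p1[paste0("scage", 1:5)])
  expect_true(all(ages[, -1] > ages[, -5]))
  p3 <- generate_cohort(500, default_dgm(), seed = 89)
  expect_false(identical(p1$bmiz1, p3$bmiz1))
})

test_that("scenario true log odds ratios are stored exactly", {
  expect_equal(default_dgm(1.1)$followup$lambda1, log(1.1))
  expect_equal(default_dgm(1.5)$followup$lambda1, log(1.5))
})
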