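## Data-generating model for the synthetic five-wave cohort:
## time-invariant profiles -> wave-1 sleep problems (logistic) ->
## bmiz trajectories (linear mixed model, quadratic in age) ->
## sleep problems waves 2..5 (logistic on lagged bmiz).

N_WAVES <- 5L

#' Parameters of the wave-1 sleep-problem model
#'
#' Logistic model for the wave-1 sleep-problem indicator:
#' `logit P(sleep_prob1 = 1) = eta0 + eta1*m_education + eta2*sex +
#' eta3*birthweight + eta4*m_age`.
#'
#' @param eta0 Intercept (log-odds).  `NA` until calibrated; see
#'   [calibrate_dgm_params()].
#' @param eta1,eta2,eta3,eta4 Log-odds coefficients for maternal education,
#'   child sex, birth weight (kg) and maternal age (years).
#' @return A list of class `"wave1_sleep_params"`.
#' @export
wave1_sleep_params <- function(eta0 = NA_real_, eta1 = -0.25, eta2 = 0.10,
                               eta3 = -0.15, eta4 = -0.01) {
  p <- list(eta0 = eta0, eta1 = eta1, eta2 = eta2, eta3 = eta3, eta4 = eta4)
  if (!all(vapply(p[-1], is.finite, logical(1)))) {
    stop_invalid("wave-1 sleep coefficients must be finite")
  }
  structure(p, class = "wave1_sleep_params")
}

#' Parameters of the bmiz trajectory model
#'
#' Linear mixed model for BMI-for-age z-scores at waves 1-5:
#' `bmiz_ij = (theta0 + a0_i) + theta1*sleep_prob1 + (theta2 + a1_i)*scage_ij
#' + (theta3 + a2_i)*scage_sq_ij + theta4*m_education + theta5*m_smoking +
#' theta6*sex + theta7*birthweight + theta8*m_age + eps_ij`, with
#' `(a0, a1, a2) ~ MVN(mu_a, Sigma_a)` per child and
#' `eps_ij ~ N(0, sigma_eps^2)` independent.
#'
#' Ages are in months, so `theta2` is per month and `theta3` per month^2;
#' the negative default `theta3` gives the concave (non-linear) trajectory.
#'
#' @param theta0 Intercept (z-score units); `NA` until calibrated.
#' @param theta1,theta4,theta5,theta6,theta7,theta8 Fixed effects of wave-1
#'   sleep problems, maternal education, maternal smoking, sex, birth weight
#'   and maternal age.
#' @param theta2,theta3 Fixed age and age-squared slopes (per month, per
#'   month^2).
#' @param sigma_eps Residual standard deviation (> 0).
#' @param mu_a Length-3 mean of the random intercept and the two random
#'   slopes.
#' @param Sigma_a 3x3 positive semi-definite covariance of the random
#'   effects.
#' @return A list of class `"bmiz_params"`.
#' @export
bmiz_params <- function(theta0 = NA_real_, theta1 = 0.10, theta2 = 0.015,
                        theta3 = -5e-5, theta4 = -0.10, theta5 = 0.15,
                        theta6 = -0.05, theta7 = 0.40, theta8 = -0.005,
                        sigma_eps = 0.45, mu_a = c(0, 0, 0),
                        Sigma_a = default_sigma_a()) {
  if (sigma_eps <= 0) stop_invalid("sigma_eps must be > 0")
  Sigma_a <- as.matrix(Sigma_a)
  if (!isTRUE(all.equal(Sigma_a, t(Sigma_a))) ||
      min(eigen(Sigma_a, symmetric = TRUE, only.values = TRUE)$values) <
        -1e-10 * max(abs(Sigma_a), 1)) {
    stop_invalid("Sigma_a must be symmetric positive semi-definite")
  }
  structure(list(theta0 = theta0, theta1 = theta1, theta2 = theta2,
                 theta3 = theta3, theta4 = theta4, theta5 = theta5,
                 theta6 = theta6, theta7 = theta7, theta8 = theta8,
                 sigma_eps = sigma_eps, mu_a = mu_a, Sigma_a = Sigma_a),
            class = "bmiz_params")
}

#' @rdname bmiz_params
#' @export
default_sigma_a <- function() {
  sds <- c(0.85, 0.004, 1e-5)
  R <- diag(3)
  R[1, 2] <- R[2, 1] <- -0.3
  diag(sds) %*% R %*% diag(sds)
}

#' Parameters of the follow-up sleep-problem model
#'
#' Logistic model for sleep problems at waves 2-5, generated sequentially:
#' `logit P(sleep_prob_j = 1) = lambda0 + lambda1*bmiz_{j-1} +
#' lambda2*m_education + lambda3*sex + lambda4*birthweight + lambda5*m_age +
#' lambda6*sleep_prob_{j-1}`.  `lambda1` is the true exposure log odds
#' ratio, the estimand of the whole study; it is stored as the exact
#' logarithm of the odds ratio, not a rounded value.
#'
#' @param lambda0 Intercept; `NA` until calibrated.
#' @param lambda1 True exposure log-OR, e.g. `log(1.1)` or `log(1.5)`.
#' @param lambda2,lambda3,lambda4,lambda5 Covariate log-odds coefficients.
#' @param lambda6 Log-odds coefficient of the lagged outcome.
#' @return A list of class `"sleep_followup_params"`.
#' @export
sleep_followup_params <- function(lambda0 = NA_real_, lambda1 = log(1.1),
                                  lambda2 = -0.20, lambda3 = 0.10,
                                  lambda4 = -0.10, lambda5 = -0.01,
                                  lambda6 = 1.2) {
  structure(list(lambda0 = lambda0, lambda1 = lambda1, lambda2 = lambda2,
                 lambda3 = lambda3, lambda4 = lambda4, lambda5 = lambda5,
                 lambda6 = lambda6),
            class = "sleep_followup_params")
}

#' Bundle of all data-generating parameters
#'
#' @param wave1_sleep A [wave1_sleep_params()] object.
#' @param bmiz A [bmiz_params()] object.
#' @param followup A [sleep_followup_params()] object.
#' @param target_prevalence Calibration target for sleep-problem prevalence
#'   (wave 1 and, on average, waves 2-5).
#' @param target_bmiz_mean Calibration target for mean bmiz at wave 1.
#' @return A list of class `"dgm_params"`.
#' @seealso [calibrate_dgm_params()], [default_dgm_params()]
#' @export
dgm_params <- function(wave1_sleep = wave1_sleep_params(),
                       bmiz = bmiz_params(),
                       followup = sleep_followup_params(),
                       target_prevalence = 0.15,
                       target_bmiz_mean = 0.30) {
  structure(list(wave1_sleep = wave1_sleep, bmiz = bmiz, followup = followup,
                 target_prevalence = target_prevalence,
                 target_bmiz_mean = target_bmiz_mean),
            class = "dgm_params")
}

the <- new.env(parent = emptyenv())

#' Default calibrated data-generating parameters
#'
#' Returns the package's default generating parameters with the three
#' intercepts (`eta0`, `theta0`, `lambda0`) calibrated so that the wave-1
#' sleep-problem prevalence is 0.15, the mean wave-1 bmiz is 0.30, and the
#' average sleep-problem prevalence over waves 2-5 is 0.15 under the chosen
#' true odds ratio.  Calibration uses its own fixed internal random stream,
#' so the resulting intercepts are reproducible constants; results are
#' cached per `true_or` within a session.
#'
#' @param true_or True exposure odds ratio (1.1 or 1.5 in the study grid;
#'   any positive value is accepted).
#' @param n_calib Monte Carlo size used for calibration.
#' @return A calibrated `"dgm_params"` object.
#' @export
default_dgm_params <- function(true_or = 1.1, n_calib = 1e5) {
  key <- sprintf("dgm_%.10g_%d", true_or, as.integer(n_calib))
  if (!is.null(the[[key]])) return(the[[key]])
  p <- dgm_params(followup = sleep_followup_params(lambda1 = log(true_or)))
  p <- calibrate_dgm_params(p, n_calib = n_calib)
  the[[key]] <- p
  p
}

#' Calibrate the three intercepts of the data-generating model
#'
#' `eta0` is found by monotone root-finding so that the Monte Carlo mean of
#' `expit(eta0 + lp)` over a calibration cohort equals the target
#' prevalence; `theta0` is set in closed form from the fixed-effect mean at
#' wave 1 (random terms have mean zero); `lambda0` is found by root-finding
#' on the exact forward-propagated prevalence of the sleep chain given the
#' calibration cohort's realised bmiz values, averaged over waves 2-5.
#'
#' @param params A `"dgm_params"` object (intercepts may be `NA`).
#' @param n_calib Calibration cohort size.
#' @param calib_seed Seed of the dedicated calibration stream.
#' @return The same object with `eta0`, `theta0`, `lambda0` filled in.
#' @export
calibrate_dgm_params <- function(params, n_calib = 1e5, calib_seed = 8601L) {
  stopifnot(inherits(params, "dgm_params"))
  prof <- sample_time_invariant(n_calib, seed = derive_seed(calib_seed, 1L))
  ws <- params$wave1_sleep
  lp1 <- ws$eta1 * prof$m_education + ws$eta2 * prof$sex +
    ws$eta3 * prof$birthweight + ws$eta4 * prof$m_age
  ws$eta0 <- calibrate_intercept(lp1, params$target_prevalence)
  params$wave1_sleep <- ws

  sleep1 <- sample_wave1_sleep(prof, ws, seed = derive_seed(calib_seed, 2L))
  ages <- sample_ages(n_calib, seed = derive_seed(calib_seed, 3L))

  bp <- params$bmiz
  fe1 <- bp$theta1 * sleep1 + bp$theta2 * ages[, 1] +
    bp$theta3 * ages[, 1]^2 + bp$theta4 * prof$m_education +
    bp$theta5 * prof$m_smoking + bp$theta6 * prof$sex +
    bp$theta7 * prof$birthweight + bp$theta8 * prof$m_age +
    bp$mu_a[1] + bp$mu_a[2] * ages[, 1] + bp$mu_a[3] * ages[, 1]^2
  bp$theta0 <- params$target_bmiz_mean - mean(fe1)
  params$bmiz <- bp

  bmiz <- sample_bmiz_trajectory(prof, sleep1, ages, bp,
                                 seed = derive_seed(calib_seed, 4L))

  fp <- params$followup
  lp_cov <- fp$lambda2 * prof$m_education + fp$lambda3 * prof$sex +
    fp$lambda4 * prof$birthweight + fp$lambda5 * prof$m_age
  ## Expected prevalence over waves 2..5 given realised bmiz and wave-1
  ## sleep, marginalising the lagged outcome exactly wave by wave.
  prev_gap <- function(l0) {
    p_prev <- sleep1
    acc <- 0
    for (j in 2:N_WAVES) {
      base <- l0 + fp$lambda1 * bmiz[, j - 1] + lp_cov
      q <- p_prev * plogis(base + fp$lambda6) + (1 - p_prev) * plogis(base)
      acc <- acc + mean(q)
      p_prev <- q
    }
    acc / (N_WAVES - 1) - params$target_prevalence
  }
  fp$lambda0 <- uniroot(prev_gap, c(-30, 30), tol = 1e-9)$root
  params$followup <- fp
  params
}

#' Draw time-invariant child and maternal profiles
#'
#' Samples the five time-invariant variables with the dependency chain
#' maternal age -> maternal education -> maternal smoking and
#' sex -> birth weight: `sex ~ Bern(0.49)`; `m_age ~ N(31, 5^2)` truncated
#' to `[18, 45]` years; `birthweight ~ N(3.30 + 0.12*(1 - sex), 0.55^2)`
#' truncated to `[1, 6]` kg; `m_education ~ Bern(expit(-0.6 +
#' 0.05*(m_age - 31)))`; `m_smoking ~ Bern(expit(-1.0 - 0.9*m_education))`.
#'
#' @param n Number of children (>= 1).
#' @param seed Integer seed; identical seeds give identical profiles.
#' @return A data frame with columns `sex`, `birthweight`, `m_age`,
#'   `m_education`, `m_smoking`.
#' @export
sample_time_invariant <- function(n, seed) {
  if (length(n) != 1 || is.na(n) || n < 1) stop_invalid("n must be >= 1")
  n <- as.integer(n)
  with_seed(seed, {
    sex <- rbinom(n, 1, 0.49)
    m_age <- rnorm_trunc(n, 31, 5, 18, 45)
    birthweight <- rnorm_trunc(n, 3.30 + 0.12 * (1 - sex), 0.55, 1.0, 6.0)
    m_education <- rbinom(n, 1, plogis(-0.6 + 0.05 * (m_age - 31)))
    m_smoking <- rbinom(n, 1, plogis(-1.0 - 0.9 * m_education))
    data.frame(sex = sex, birthweight = birthweight, m_age = m_age,
               m_education = m_education, m_smoking = m_smoking)
  })
}

#' Draw ages at the five waves
#'
#' Wave-1 age is `N(57, 3^2)` months truncated to `[48, 72]`; each
#' subsequent wave adds a gap of `24 + N(0, 1)` months (truncated to
#' `[20, 28]` so ages are strictly increasing), reflecting data collection
#' every two years.
#'
#' @param n Number of children.
#' @param seed Integer seed.
#' @return An `n x 5` matrix of ages in months.
#' @export
sample_ages <- function(n, seed) {
  with_seed(seed, {
    ages <- matrix(0, n, N_WAVES)
    ages[, 1] <- rnorm_trunc(n, 57, 3, 48, 72)
    for (j in 2:N_WAVES) {
      ages[, j] <- ages[, j - 1] + rnorm_trunc(n, 24, 1, 20, 28)
    }
    ages
  })
}

#' Draw wave-1 sleep-problem indicators
#'
#' @param profiles Data frame from [sample_time_invariant()].
#' @param params A [wave1_sleep_params()] object with finite `eta0`.
#' @param seed Integer seed.
#' @return Integer 0/1 vector of length `nrow(profiles)`.
#' @export
sample_wave1_sleep <- function(profiles, params, seed) {
  stopifnot(inherits(params, "wave1_sleep_params"))
  if (!is.finite(params$eta0)) stop_invalid("eta0 has not been calibrated")
  lp <- params$eta0 + params$eta1 * profiles$m_education +
    params$eta2 * profiles$sex + params$eta3 * profiles$birthweight +
    params$eta4 * profiles$m_age
  with_seed(seed, rbinom(nrow(profiles), 1, plogis(lp)))
}

#' Draw bmiz trajectories for waves 1-5
#'
#' @param profiles Data frame of time-invariant profiles.
#' @param wave1_sleep 0/1 vector of wave-1 sleep problems.
#' @param ages `n x 5` matrix of ages in months, strictly increasing per row.
#' @param params A [bmiz_params()] object with finite `theta0`.
#' @param seed Integer seed.
#' @return An `n x 5` matrix of bmiz values.
#' @export
sample_bmiz_trajectory <- function(profiles, wave1_sleep, ages, params, seed) {
  stopifnot(inherits(params, "bmiz_params"))
  if (!is.finite(params$theta0)) stop_invalid("theta0 has not been calibrated")
  n <- nrow(profiles)
  if (!is.matrix(ages) || nrow(ages) != n || ncol(ages) != N_WAVES) {
    stop_invalid("ages must be an n x %d matrix", N_WAVES)
  }
  if (any(ages[, -1] <= ages[, -N_WAVES])) {
    stop_invalid("ages must be strictly increasing across waves")
  }
  with_seed(seed, {
    a <- rmvnorm_rows(matrix(rep(params$mu_a, each = n), n, 3), params$Sigma_a)
    fixed_i <- params$theta0 + params$theta1 * wave1_sleep +
      params$theta4 * profiles$m_education +
      params$theta5 * profiles$m_smoking + params$theta6 * profiles$sex +
      params$theta7 * profiles$birthweight + params$theta8 * profiles$m_age
    bmiz <- (fixed_i + a[, 1]) +
      (params$theta2 + a[, 2]) * ages +
      (params$theta3 + a[, 3]) * ages^2 +
      matrix(rnorm(n * N_WAVES, 0, params$sigma_eps), n, N_WAVES)
    bmiz
  })
}

#' Draw sleep-problem indicators for waves 2-5
#'
#' Samples sequentially in wave order: the wave-`j` indicator is Bernoulli
#' with log-odds `lambda0 + lambda1*bmiz_{j-1} + covariate terms +
#' lambda6*sleep_prob_{j-1}`.
#'
#' @param panel Data frame holding `bmiz1`..`bmiz4`, `sleep_prob1` and the
#'   time-invariant covariates.
#' @param params A [sleep_followup_params()] object with finite `lambda0`.
#' @param seed Integer seed.
#' @return An `n x 4` integer matrix (waves 2-5).
#' @export
sample_sleep_followup <- function(panel, params, seed) {
  stopifnot(inherits(params, "sleep_followup_params"))
  if (!is.finite(params$lambda0)) stop_invalid("lambda0 has not been calibrated")
  need <- c(paste0("bmiz", 1:4), "sleep_prob1", "m_education", "sex",
            "birthweight", "m_age")
  miss <- setdiff(need, names(panel))
  if (length(miss)) stop_invalid("panel lacks columns: %s",
                                 paste(miss, collapse = ", "))
  if (anyNA(panel[paste0("bmiz", 1:4)])) {
    stop_invalid("bmiz waves 1-4 must be complete to generate the outcome")
  }
  n <- nrow(panel)
  lp_cov <- params$lambda0 + params$lambda2 * panel$m_education +
    params$lambda3 * panel$sex + params$lambda4 * panel$birthweight +
    params$lambda5 * panel$m_age
  with_seed(seed, {
    out <- matrix(0L, n, N_WAVES - 1)
    prev <- panel$sleep_prob1
    for (j in 2:N_WAVES) {
      lp <- lp_cov + params$lambda1 * panel[[paste0("bmiz", j - 1)]] +
        params$lambda6 * prev
      out[, j - 1] <- rbinom(n, 1, plogis(lp))
      prev <- out[, j - 1]
    }
    out
  })
}

#' Generate a complete five-wave cohort panel
#'
#' Composes the four sampling stages (time-invariant profiles, wave-1 sleep,
#' bmiz trajectories, follow-up sleep) under per-stage substreams derived
#' from `seed`.  The result is a wide panel, one row per child, with no
#' missing cells; `scage_sq` columns are the exact squares of the `scage`
#' columns.
#'
#' @param n Cohort size (>= 1).
#' @param dgm A calibrated [dgm_params()] object; defaults to
#'   [default_dgm_params()].
#' @param seed Integer master seed for this cohort.
#' @return A data frame of class `"cohort_panel"` with columns `id`, the
#'   five time-invariant variables, and `scage1..5`, `scage_sq1..5`,
#'   `bmiz1..5`, `sleep_prob1..5`.
#' @export
generate_cohort <- function(n, dgm = default_dgm_params(), seed = 1L) {
  if (length(n) != 1 || is.na(n) || n < 1) stop_invalid("n must be >= 1")
  stopifnot(inherits(dgm, "dgm_params"))
  prof <- sample_time_invariant(n, seed = derive_seed(seed, 11L))
  sleep1 <- sample_wave1_sleep(prof, dgm$wave1_sleep,
                               seed = derive_seed(seed, 12L))
  ages <- sample_ages(n, seed = derive_seed(seed, 13L))
  bmiz <- sample_bmiz_trajectory(prof, sleep1, ages, dgm$bmiz,
                                 seed = derive_seed(seed, 14L))
  panel <- cbind(data.frame(id = seq_len(n)), prof)
  for (j in 1:N_WAVES) panel[[wave_col("scage", j)]] <- ages[, j]
  for (j in 1:N_WAVES) panel[[wave_col("scage_sq", j)]] <- ages[, j]^2
  for (j in 1:N_WAVES) panel[[wave_col("bmiz", j)]] <- bmiz[, j]
  panel$sleep_prob1 <- sleep1
  sleep_rest <- sample_sleep_followup(panel, dgm$followup,
                                      seed = derive_seed(seed, 15L))
  for (j in 2:N_WAVES) panel[[wave_col("sleep_prob", j)]] <- sleep_rest[, j - 1]
  class(panel) <- c("cohort_panel", "data.frame")
  panel
}
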