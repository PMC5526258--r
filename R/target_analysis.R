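## Target analysis: marginal logistic regression of sleep problems at wave
## j on bmiz at wave j-1 plus confounders and the lagged outcome, fitted by
## generalized estimating equations with an unstructured working
## correlation and robust (sandwich) standard errors.

ANALYSIS_COVARIATES <- c("m_education", "sex", "birthweight", "m_age")

#' Build the long analysis table
#'
#' One row per child and wave `j in 2..5`, carrying the outcome
#' `sleep_prob_j`, the lagged exposure `bmiz_{j-1}`, the confounders, and
#' the lagged outcome `sleep_prob_{j-1}`.  bmiz at wave 5 never enters the
#' analysis.  Rows are ordered by `(id, wave)`.
#'
#' @param panel A complete or completed cohort panel.
#' @return A data frame with columns `id`, `wave`, `y`, `bmiz_prev`,
#'   the four confounders, and `sleep_prev`.
#' @export
build_analysis_long <- function(panel) {
  need <- c("id", ANALYSIS_COVARIATES, paste0("bmiz", 1:4),
            paste0("sleep_prob", 1:5))
  miss <- setdiff(need, names(panel))
  if (length(miss)) stop_invalid("panel lacks columns: %s",
                                 paste(miss, collapse = ", "))
  blocks <- lapply(2:5, function(j) {
    data.frame(id = panel$id, wave = j,
               y = panel[[paste0("sleep_prob", j)]],
               bmiz_prev = panel[[paste0("bmiz", j - 1)]],
               panel[ANALYSIS_COVARIATES],
               sleep_prev = panel[[paste0("sleep_prob", j - 1)]])
  })
  long <- do.call(rbind, blocks)
  long[order(long$id, long$wave), , drop = FALSE]
}

#' Fit the target GEE model
#'
#' Marginal logistic model `y ~ bmiz_prev + m_education + sex +
#' birthweight + m_age + sleep_prev` for clustered binary outcomes, with
#' an unstructured 4x4 working correlation over waves 2-5 estimated from
#' Pearson residuals, Fisher-scoring updates, and robust sandwich standard
#' errors.  Clusters must be balanced (every child contributes all four
#' waves); the study pipelines guarantee this, since complete-case
#' analysis drops whole children.
#'
#' If the estimated unstructured correlation is not positive-definite in
#' some iteration, the fit falls back to an exchangeable structure for
#' that dataset and flags it.
#'
#' @param long Output of [build_analysis_long()], with no missing values.
#' @param corstr `"unstructured"` (default), `"exchangeable"` or
#'   `"independence"`.
#' @param maxit,tol Scoring-iteration control.
#' @param beta_init Optional starting coefficients (e.g. from a fit on a
#'   neighbouring imputation); by default an independence logistic fit.
#' @return A list of class `"gee_estimate"`: `beta1` (log-OR for
#'   `bmiz_prev`), `se`, `ci_low`, `ci_high`, `converged`, `n_clusters`,
#'   plus the full coefficient vector, robust covariance, working
#'   correlation and a `fallback` flag.
#' @export
fit_gee <- function(long, corstr = c("unstructured", "exchangeable",
                                     "independence"),
                    maxit = 50L, tol = 1e-8, beta_init = NULL) {
  corstr <- match.arg(corstr)
  if (anyNA(long)) stop_invalid("analysis table contains missing values")
  if (length(unique(long$id)) < 2) stop_invalid("need at least 2 clusters")
  long <- long[order(long$id, long$wave), , drop = FALSE]
  tab <- tabulate(match(long$id, unique(long$id)))
  if (any(tab != 4)) {
    stop_invalid("unbalanced clusters: every child must contribute 4 waves")
  }
  X <- cbind(`(Intercept)` = 1, bmiz_prev = long$bmiz_prev,
             m_education = long$m_education, sex = long$sex,
             birthweight = long$birthweight, m_age = long$m_age,
             sleep_prev = long$sleep_prev)
  y <- long$y
  n_cl <- length(y) / 4L

  beta <- beta_init %||% suppressWarnings(
    glm.fit(X, y, family = binomial())$coefficients)
  if (anyNA(beta)) stop_invalid("initial logistic fit is rank-deficient")

  fit <- gee_core(X, y, 4L,
                  match(corstr, c("independence", "exchangeable",
                                  "unstructured")) - 1L,
                  beta, as.integer(maxit), tol)
  beta <- drop(fit$beta)
  names(beta) <- colnames(X)
  V <- fit$vcov
  dimnames(V) <- list(colnames(X), colnames(X))

  b1 <- beta[["bmiz_prev"]]
  se1 <- sqrt(V["bmiz_prev", "bmiz_prev"])
  structure(list(beta1 = b1, se = se1,
                 ci_low = b1 - qnorm(0.975) * se1,
                 ci_high = b1 + qnorm(0.975) * se1,
                 converged = fit$converged, n_clusters = n_cl,
                 coefficients = beta, vcov = V,
                 working_correlation = fit$R, corstr = corstr,
                 fallback = fit$fallback),
            class = "gee_estimate")
}

#' Complete-case GEE estimate
#'
#' Drops every child with any missing bmiz at waves 2-4 (missingness at
#' wave 5 is irrelevant, as bmiz5 never enters the analysis) and fits the
#' target GEE on the remaining children.
#'
#' @param masked A `"missingness_pattern"` or a panel with `NA` holes in
#'   bmiz waves 2-5.
#' @param ... Passed to [fit_gee()].
#' @return A `"gee_estimate"`.
#' @export
complete_case_estimate <- function(masked, ...) {
  panel <- as_masked_panel(masked)
  keep <- !is.na(panel$bmiz2) & !is.na(panel$bmiz3) & !is.na(panel$bmiz4)
  if (sum(keep) < 2) stop_invalid("fewer than 2 complete cases remain")
  fit_gee(build_analysis_long(panel[keep, , drop = FALSE]), ...)
}

#' Pool estimates across imputations by Rubin's rules
#'
#' The pooled estimate is the mean of the per-imputation estimates; the
#' total variance is `T = W + (1 + 1/m) B` with `W` the mean squared
#' standard error and `B` the between-imputation sample variance.  The
#' confidence interval uses Rubin's classic degrees of freedom
#' `(m - 1) (1 + W / ((1 + 1/m) B))^2`; when `B = 0` the normal interval
#' is used.
#'
#' @param estimates Either a list of `"gee_estimate"` objects (only
#'   converged ones are pooled; the number dropped is reported) or a
#'   numeric vector of estimates.
#' @param ses Standard errors, required when `estimates` is numeric.
#' @param conf_level Confidence level for the pooled interval.
#' @return A list of class `"pooled_estimate"` with `estimate`, `W`, `B`,
#'   `T`, `se`, `df`, `ci_low`, `ci_high`, `m`, `n_dropped`.
#' @export
rubin_pool <- function(estimates, ses = NULL, conf_level = 0.95) {
  n_dropped <- 0L
  if (is.list(estimates) && all(vapply(estimates, inherits, logical(1),
                                       "gee_estimate"))) {
    ok <- vapply(estimates, function(e) isTRUE(e$converged), logical(1))
    n_dropped <- sum(!ok)
    ses <- vapply(estimates[ok], function(e) e$se, numeric(1))
    estimates <- vapply(estimates[ok], function(e) e$beta1, numeric(1))
  }
  m <- length(estimates)
  if (m < 2) stop_invalid("need at least 2 estimates to pool")
  if (length(ses) != m) stop_invalid("estimates and ses must have equal length")
  est <- mean(estimates)
  W <- mean(ses^2)
  B <- stats::var(estimates)
  Tv <- W + (1 + 1 / m) * B
  df <- if (B > 0) (m - 1) * (1 + W / ((1 + 1 / m) * B))^2 else Inf
  se <- sqrt(Tv)
  q <- if (is.finite(df)) qt(1 - (1 - conf_level) / 2, df) else
    qnorm(1 - (1 - conf_level) / 2)
  structure(list(estimate = est, W = W, B = B, T = Tv, se = se, df = df,
                 ci_low = est - q * se, ci_high = est + q * se,
                 m = m, n_dropped = n_dropped),
            class = "pooled_estimate")
}

#' Pooled GEE estimate from a completed set
#'
#' Convenience wrapper: fits the target GEE on each completed panel and
#' pools by Rubin's rules.
#'
#' @param cs A `"completed_set"`.
#' @param ... Passed to [fit_gee()].
#' @return A `"pooled_estimate"`.
#' @export
pooled_gee_estimate <- function(cs, ...) {
  stopifnot(inherits(cs, "completed_set"))
  ## Completed panels share every column except the imputed bmiz values,
  ## so the long table is built once and only the lagged exposure column
  ## is refreshed per imputation; successive fits warm-start from the
  ## previous coefficients.
  first <- cs$panels[[1]][order(cs$panels[[1]]$id), , drop = FALSE]
  long <- build_analysis_long(first)
  fits <- vector("list", length(cs$panels))
  beta0 <- NULL
  for (k in seq_along(cs$panels)) {
    pk <- cs$panels[[k]][order(cs$panels[[k]]$id), , drop = FALSE]
    long$bmiz_prev <- as.vector(t(as.matrix(pk[paste0("bmiz", 1:4)])))
    fits[[k]] <- fit_gee(long, ..., beta_init = beta0)
    if (fits[[k]]$converged) beta0 <- fits[[k]]$coefficients
  }
  rubin_pool(fits)
}
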