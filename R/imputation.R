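## Multiple-imputation engines.  Only bmiz at waves 2-5 is ever incomplete,
## so every univariate imputation model is a Bayesian normal linear
## regression; binary variables enter only as complete predictors.

IMP_VARS <- c(paste0("bmiz", 1:5), paste0("sleep_prob", 1:5),
              "m_education", "m_smoking", "sex", "birthweight", "m_age")
TIME_INVARIANT_PREDICTORS <- c("m_education", "sex", "birthweight", "m_age",
                               "m_smoking")

#' Configuration of the imputation engines
#'
#' @param m Number of imputations (>= 2; 50 is the study default).
#' @param fcs_cycles Chained-equation cycles per imputation for [fcs_impute()].
#' @param da_burnin Burn-in iterations of the data-augmentation chain in
#'   [mvni_impute()].
#' @param da_thin Iterations between saved imputations after burn-in.
#' @param twofold_among Among-time iterations of [twofold_fcs_impute()].
#' @param twofold_within Within-time cycles at each time point.
#' @param window_width Time-window half-width of the two-fold algorithm
#'   (1 = immediately adjacent waves, 2 = two adjacent waves).
#' @return A list of class `"imputation_config"`.
#' @export
imputation_config <- function(m = 50L, fcs_cycles = 10L, da_burnin = 200L,
                              da_thin = 100L, twofold_among = 10L,
                              twofold_within = 1L, window_width = 1L) {
  cfg <- list(m = as.integer(m), fcs_cycles = as.integer(fcs_cycles),
              da_burnin = as.integer(da_burnin), da_thin = as.integer(da_thin),
              twofold_among = as.integer(twofold_among),
              twofold_within = as.integer(twofold_within),
              window_width = as.integer(window_width))
  if (cfg$m < 2) stop_invalid("m must be >= 2")
  if (any(unlist(cfg[-1]) < 1)) stop_invalid("iteration counts must be >= 1")
  structure(cfg, class = "imputation_config")
}

## Accept either a missingness_pattern or a panel with NA holes.
as_masked_panel <- function(x) {
  if (inherits(x, "missingness_pattern")) x <- x$panel
  bmiz_late <- paste0("bmiz", 2:5)
  other <- setdiff(IMP_VARS, bmiz_late)
  if (anyNA(x[other])) {
    stop_invalid("holes are only supported in bmiz waves 2-5")
  }
  if (anyNA(x[["bmiz1"]])) stop_invalid("bmiz at wave 1 must be complete")
  x
}

#' Posterior-predictive draw from a Bayesian normal linear model
#'
#' Fits `y ~ X` on the observed rows under the standard noninformative
#' prior, draws the residual variance from its scaled inverse-chi-square
#' posterior and the coefficients from their conditional normal posterior,
#' and returns one posterior-predictive draw of the response for each row
#' of `X_missing`.  This "proper imputation" step underlies the FCS and
#' two-fold FCS engines.
#'
#' A tiny ridge (`1e-8` times the mean diagonal of the cross-product) is
#' added before inversion; if the design is rank-deficient beyond that, an
#' error names the offending columns.
#'
#' @param y_observed Response values on the observed rows.
#' @param X_observed Design matrix on the observed rows (include the
#'   intercept column yourself).
#' @param X_missing Design matrix on the rows to be imputed (may have zero
#'   rows, in which case an empty vector is returned).
#' @param seed Optional seed; by default the ambient RNG stream is used.
#' @return Numeric vector of imputed values, one per row of `X_missing`.
#' @export
bayesian_linear_draw <- function(y_observed, X_observed, X_missing,
                                 seed = NULL) {
  if (!is.null(seed)) return(with_seed(seed, bayesian_linear_draw(
    y_observed, X_observed, X_missing)))
  n_mis <- NROW(X_missing)
  if (n_mis == 0) return(numeric(0))
  X <- as.matrix(X_observed)
  n <- nrow(X)
  p <- ncol(X)
  if (n <= p) stop_invalid("need more observed rows (%d) than predictors (%d)", n, p)
  qrX <- qr(X)
  if (qrX$rank < p) {
    bad <- colnames(X)[qrX$pivot[seq(qrX$rank + 1, p)]] %||% "unnamed"
    stop_invalid("degenerate imputation model: collinear predictors (%s)",
                 paste(bad, collapse = ", "))
  }
  XtX <- crossprod(X)
  XtX <- XtX + diag(1e-8 * mean(diag(XtX)), p)
  ch <- tryCatch(chol(XtX), error = function(e) NULL)
  if (is.null(ch)) {
    stop_invalid("degenerate imputation model: cross-product not positive definite")
  }
  beta_hat <- backsolve(ch, backsolve(ch, crossprod(X, y_observed),
                                      transpose = TRUE))
  rss <- sum((y_observed - X %*% beta_hat)^2)
  df <- n - p
  sigma2_star <- rss / rchisq(1, df)
  beta_star <- beta_hat + backsolve(ch, rnorm(p)) * sqrt(sigma2_star)
  drop(as.matrix(X_missing) %*% beta_star) +
    rnorm(n_mis, 0, sqrt(sigma2_star))
}

## Initialise holes by drawing with replacement from the observed margin.
init_holes <- function(Z, hole) {
  for (v in names(hole)) {
    h <- hole[[v]]
    if (any(h)) Z[h, v] <- sample(Z[!h, v], sum(h), replace = TRUE)
  }
  Z
}

## Build the numeric working matrix and hole map from a masked panel.
masked_matrix <- function(panel) {
  Z <- as.matrix(panel[IMP_VARS])
  storage.mode(Z) <- "double"
  hole <- lapply(paste0("bmiz", 2:5), function(v) is.na(Z[, v]))
  names(hole) <- paste0("bmiz", 2:5)
  list(Z = Z, hole = hole)
}

## 0-based index plan for the compiled chained-draw kernel.
chained_plan <- function(mm, preds, active) {
  cols <- colnames(mm$Z)
  list(
    targets = vapply(active, function(v) match(v, cols) - 1L, integer(1)),
    holes = lapply(active, function(v) which(mm$hole[[v]]) - 1L),
    preds = lapply(active, function(v) match(preds[[v]], cols) - 1L)
  )
}

## Assemble a completed_set from imputed matrices.
completed_set <- function(panel, imputed, method, width, seed, predictors) {
  panels <- lapply(imputed, function(Z) {
    out <- panel
    for (v in paste0("bmiz", 2:5)) out[[v]] <- Z[, v]
    out
  })
  structure(list(method = method, width = width, panels = panels,
                 seed = seed, predictors = predictors),
            class = "completed_set")
}

#' Impute by fully conditional specification (chained equations)
#'
#' Treats each wave's bmiz as a distinct variable ("just another
#' variable"): for each imputation, holes are initialised from the
#' observed margins and the engine cycles `fcs_cycles` times over
#' `bmiz2..bmiz5`, drawing each from a Bayesian linear model whose
#' predictors are bmiz at all other waves (current values), the sleep
#' problem indicators at all five waves, and the time-invariant variables
#' including the auxiliary maternal smoking.
#'
#' @param masked A `"missingness_pattern"` or a panel with `NA` holes
#'   confined to bmiz waves 2-5.
#' @param config An [imputation_config()].
#' @param seed Integer seed; each imputation runs in its own substream, so
#'   results do not depend on execution order.
#' @return A `"completed_set"`: `m` completed panels plus provenance.
#' @export
fcs_impute <- function(masked, config = imputation_config(), seed = 1L) {
  panel <- as_masked_panel(masked)
  mm <- masked_matrix(panel)
  preds <- lapply(2:5, function(t) {
    c(paste0("bmiz", setdiff(1:5, t)), paste0("sleep_prob", 1:5),
      TIME_INVARIANT_PREDICTORS)
  })
  names(preds) <- paste0("bmiz", 2:5)
  active <- names(which(vapply(mm$hole, any, logical(1))))
  plan <- chained_plan(mm, preds, active)
  schedule <- rep(seq_along(active), times = config$fcs_cycles) - 1L
  imputed <- lapply(seq_len(config$m), function(k) {
    with_seed(derive_seed(seed, 300L, k), {
      Z <- init_holes(mm$Z, mm$hole)
      if (length(active)) {
        Z <- chained_run(Z, plan$targets, plan$holes, plan$preds, schedule)
      }
      dimnames(Z) <- dimnames(mm$Z)
      Z
    })
  })
  completed_set(panel, imputed, "FCS", NULL, seed, preds)
}

#' Predictor waves of the two-fold FCS time block
#'
#' For target time `t` and half-width `w`, the block is
#' `{t - w, ..., t + w}` intersected with the observed waves 1..5.
#'
#' @param t Target wave.
#' @param width Window half-width.
#' @return Integer vector of waves in the block.
#' @export
twofold_window <- function(t, width) {
  intersect(seq(t - width, t + width), 1:5)
}

#' Impute by the two-fold fully conditional specification algorithm
#'
#' Exploits the temporal ordering: bmiz at time `t` is imputed using only
#' information from the time block [twofold_window()] around `t` — bmiz and
#' sleep problems at those waves (current values) — plus all time-invariant
#' variables.  Each imputation initialises holes from the observed margins,
#' then runs `twofold_among` among-time iterations, each sweeping the time
#' points in order with `twofold_within` within-time cycles.
#'
#' @inheritParams fcs_impute
#' @return A `"completed_set"` with the window width recorded.
#' @export
twofold_fcs_impute <- function(masked, config = imputation_config(),
                               seed = 1L) {
  panel <- as_masked_panel(masked)
  mm <- masked_matrix(panel)
  w <- config$window_width
  preds <- lapply(2:5, function(t) {
    waves <- twofold_window(t, w)
    c(paste0("bmiz", setdiff(waves, t)), paste0("sleep_prob", waves),
      TIME_INVARIANT_PREDICTORS)
  })
  names(preds) <- paste0("bmiz", 2:5)
  active <- names(which(vapply(mm$hole, any, logical(1))))
  plan <- chained_plan(mm, preds, active)
  ## among-iterations sweep the time points in order, repeating each
  ## incomplete time point `twofold_within` times
  one_sweep <- rep(seq_along(active), each = config$twofold_within)
  schedule <- rep(one_sweep, times = config$twofold_among) - 1L
  imputed <- lapply(seq_len(config$m), function(k) {
    with_seed(derive_seed(seed, 400L + w, k), {
      Z <- init_holes(mm$Z, mm$hole)
      if (length(active)) {
        Z <- chained_run(Z, plan$targets, plan$holes, plan$preds, schedule)
      }
      dimnames(Z) <- dimnames(mm$Z)
      Z
    })
  })
  completed_set(panel, imputed, "TWOFOLD", w, seed, preds)
}
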