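## Imposition of MCAR and MAR missingness on bmiz at waves 2-5, combining
## monotone dropout ("missing for all subsequent waves", model A) with
## intermittent missingness (model B), with wave-specific intercepts
## calibrated by root-finding so realized proportions hit their targets.

#' Log odds ratios of the MAR missingness models
#'
#' Returns the odds ratios of the two missingness models for the named MAR
#' scenario: model A governs dropout (missing for all subsequent waves),
#' model B intermittent missingness.  Predictors are sleep problems at
#' waves 1 and 5 and maternal smoking.  The strong-scenario odds ratios are
#' the squares of the weak ones (log-odds doubled), rounded to two
#' decimals.
#'
#' @param mechanism `"MAR_weak"` or `"MAR_strong"`.
#' @return A list of class `"mar_params"` with components `or_A` and `or_B`
#'   (named length-3 vectors: `sleep_prob1`, `sleep_prob5`, `m_smoking`).
#' @export
mar_params <- function(mechanism = c("MAR_weak", "MAR_strong")) {
  mechanism <- match.arg(mechanism)
  tab <- list(
    MAR_weak = list(or_A = c(sleep_prob1 = 1.67, sleep_prob5 = 1.64,
                             m_smoking = 1.61),
                    or_B = c(sleep_prob1 = 1.61, sleep_prob5 = 1.58,
                             m_smoking = 1.58)),
    MAR_strong = list(or_A = c(sleep_prob1 = 2.80, sleep_prob5 = 2.70,
                               m_smoking = 2.60),
                      or_B = c(sleep_prob1 = 2.60, sleep_prob5 = 2.50,
                               m_smoking = 2.50))
  )
  structure(tab[[mechanism]], class = "mar_params", mechanism = mechanism)
}

#' Specification of a missingness scenario
#'
#' @param mechanism One of `"MCAR"`, `"MAR_weak"`, `"MAR_strong"`.
#' @param target_final Proportion of bmiz missing at wave 5 (0.25 or 0.50
#'   in the study grid; any value in `[0, 1)` is accepted).
#' @param per_wave_targets Cumulative missing proportions for waves 2-5.
#'   Defaults to a linear ramp `target_final * (1:4)/4`, ending at
#'   `target_final`; must be non-decreasing.
#' @param dropout_share Fraction of each wave's new missingness attributed
#'   to dropout (model A) rather than intermittent missingness (model B).
#' @return A list of class `"missingness_spec"`.
#' @export
missingness_spec <- function(mechanism = c("MCAR", "MAR_weak", "MAR_strong"),
                             target_final = 0.25,
                             per_wave_targets = NULL,
                             dropout_share = 0.5) {
  mechanism <- match.arg(mechanism)
  if (target_final < 0 || target_final >= 1) {
    stop_invalid("target_final must be in [0, 1)")
  }
  if (is.null(per_wave_targets)) {
    per_wave_targets <- target_final * (1:4) / 4
  }
  if (length(per_wave_targets) != 4 || is.unsorted(per_wave_targets) ||
      abs(per_wave_targets[4] - target_final) > 1e-12) {
    stop_invalid("per_wave_targets must be 4 non-decreasing proportions ending at target_final")
  }
  if (dropout_share < 0 || dropout_share > 1) {
    stop_invalid("dropout_share must be in [0, 1]")
  }
  structure(list(mechanism = mechanism, target_final = target_final,
                 per_wave_targets = per_wave_targets,
                 dropout_share = dropout_share,
                 mar_params = if (mechanism != "MCAR") mar_params(mechanism)),
            class = "missingness_spec")
}

#' Calibrate a logistic intercept to an expected proportion
#'
#' Finds the intercept `c` such that `mean(plogis(c + lp)) == target` by
#' monotone root-finding, to absolute tolerance `1e-6` on the proportion.
#' This is the "chosen by iteration" step used for every missingness model
#' and for the outcome-model intercepts of the data-generating model.
#'
#' @param lp Vector of linear-predictor values excluding the intercept.
#' @param target Target proportion, strictly between 0 and 1.
#' @param tol Tolerance on the achieved proportion.
#' @return The calibrated intercept (scalar).
#' @export
calibrate_intercept <- function(lp, target, tol = 1e-6) {
  if (length(target) != 1 || is.na(target) || target <= 0 || target >= 1) {
    stop_invalid("target must be strictly between 0 and 1")
  }
  if (!all(is.finite(lp))) stop_invalid("linear predictor must be finite")
  f <- function(c0) mean(plogis(c0 + lp)) - target
  lo <- qlogis(target) - max(abs(lp)) - 1
  hi <- qlogis(target) + max(abs(lp)) + 1
  uniroot(f, c(lo, hi), tol = tol / 10)$root
}

#' Impose missingness on bmiz waves 2-5
#'
#' Dispatches on `spec$mechanism` to [apply_mar()] or [apply_mcar()].
#'
#' @param panel A complete cohort panel from [generate_cohort()].
#' @param spec A [missingness_spec()].
#' @param seed Integer seed.
#' @return A `"missingness_pattern"` object: list with `R` (an `n x 5` 0/1
#'   matrix, column 1 all zero), `panel` (the panel with masked bmiz cells
#'   set to `NA`), and `spec`.
#' @export
apply_missingness <- function(panel, spec, seed) {
  if (spec$mechanism == "MCAR") apply_mcar(panel, spec, seed)
  else apply_mar(panel, spec, seed)
}

#' @rdname apply_missingness
#' @details
#' Under MAR, at each wave transition `j -> j+1` children not already
#' dropped out are first subjected to model A (dropout: bmiz missing at all
#' waves `> j`), with log-odds `nu0_j + log(OR)` terms in wave-1 sleep
#' problems, wave-5 sleep problems and maternal smoking; among the
#' remaining non-dropouts, model B assigns intermittent missingness at wave
#' `j+1` analogously.  The intercepts are re-calibrated for each dataset so
#' the expected cumulative missing proportion at each wave equals the
#' spec's target, split between the two models by `dropout_share`.
#' @export
apply_mar <- function(panel, spec, seed) {
  if (!spec$mechanism %in% c("MAR_weak", "MAR_strong")) {
    stop_invalid("apply_mar requires a MAR mechanism")
  }
  lor_A <- log(spec$mar_params$or_A)
  lor_B <- log(spec$mar_params$or_B)
  lp_A <- lor_A[1] * panel$sleep_prob1 + lor_A[2] * panel$sleep_prob5 +
    lor_A[3] * panel$m_smoking
  lp_B <- lor_B[1] * panel$sleep_prob1 + lor_B[2] * panel$sleep_prob5 +
    lor_B[3] * panel$m_smoking
  impose_two_pattern(panel, spec, lp_A, lp_B, seed)
}

#' @rdname apply_missingness
#' @details
#' Under MCAR the same two-pattern machinery is used with intercept-only
#' models, so dropout and intermittent assignments are independent of all
#' data values.
#' @export
apply_mcar <- function(panel, spec, seed) {
  if (spec$mechanism != "MCAR") stop_invalid("apply_mcar requires mechanism MCAR")
  zero <- rep(0, nrow(panel))
  impose_two_pattern(panel, spec, zero, zero, seed)
}

## Shared engine: model-A dropout then model-B intermittent missingness at
## each wave, with per-dataset expected-proportion calibration.
impose_two_pattern <- function(panel, spec, lp_A, lp_B, seed) {
  n <- nrow(panel)
  R <- matrix(0L, n, N_WAVES)
  dropped <- rep(FALSE, n)
  with_seed(seed, {
    for (w in 2:N_WAVES) {
      target_n <- spec$per_wave_targets[w - 1] * n
      new_n <- max(target_n - sum(dropped), 0)
      n_A <- spec$dropout_share * new_n
      n_B <- (1 - spec$dropout_share) * new_n
      ## model A among current non-dropouts
      elig <- which(!dropped)
      if (n_A > 0 && length(elig) > 0) {
        pr_target <- min(n_A / length(elig), 1 - 1e-9)
        if (pr_target > 0) {
          c0 <- calibrate_intercept(lp_A[elig], pr_target)
          new_drop <- elig[runif(length(elig)) < plogis(c0 + lp_A[elig])]
          dropped[new_drop] <- TRUE
        }
      }
      ## model B among remaining non-dropouts: missing at wave w only
      elig <- which(!dropped)
      inter <- integer(0)
      if (n_B > 0 && length(elig) > 0) {
        pr_target <- min(n_B / length(elig), 1 - 1e-9)
        if (pr_target > 0) {
          c0 <- calibrate_intercept(lp_B[elig], pr_target)
          inter <- elig[runif(length(elig)) < plogis(c0 + lp_B[elig])]
        }
      }
      R[dropped | seq_len(n) %in% inter, w] <- 1L
    }
  })
  masked <- panel
  for (w in 2:N_WAVES) {
    masked[[wave_col("bmiz", w)]][R[, w] == 1L] <- NA_real_
  }
  structure(list(R = R, panel = masked, spec = spec),
            class = "missingness_pattern")
}

#' Proportion of children with missing bmiz at a wave
#'
#' @param pattern A `"missingness_pattern"` object.
#' @param wave Wave index in 2..5.
#' @return The mean of the missingness indicator at that wave.
#' @export
missing_fraction <- function(pattern, wave) {
  stopifnot(inherits(pattern, "missingness_pattern"))
  if (length(wave) != 1 || !wave %in% 2:N_WAVES) {
    stop_invalid("wave must be one of 2..%d", N_WAVES)
  }
  mean(pattern$R[, wave])
}
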