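## Performance measures computed across replicate estimates of the
## exposure log odds ratio for one scenario x method cell.

#' Replicate estimates for one scenario and method
#'
#' @param true_log_or True exposure log odds ratio used in generation.
#' @param estimates,ses,ci_low,ci_high Per-replicate estimate, standard
#'   error and 95% confidence bounds (equal lengths, >= 2, finite).
#' @return A list of class `"scenario_result"`.
#' @export
scenario_result <- function(true_log_or, estimates, ses, ci_low, ci_high) {
  n <- length(estimates)
  if (n < 2) stop_invalid("need at least 2 replicates")
  if (length(ses) != n || length(ci_low) != n || length(ci_high) != n) {
    stop_invalid("replicate vectors must have equal length")
  }
  if (!all(is.finite(c(true_log_or, estimates, ses, ci_low, ci_high)))) {
    stop_invalid("replicate entries must be finite")
  }
  structure(list(true_log_or = true_log_or, estimates = estimates,
                 ses = ses, ci_low = ci_low, ci_high = ci_high,
                 n_replicates = n),
            class = "scenario_result")
}

#' Summarise replicate performance
#'
#' Computes the seven performance measures: absolute bias
#' `|mean(est) - true|`, relative bias `100 * bias / |true|` (%), empirical
#' SE (standard deviation of the estimates), model-based SE (mean of the
#' estimated standard errors), coverage (% of replicates whose interval
#' contains the truth), RMSE `sqrt(bias^2 + empirical_se^2)`, and the
#' Monte Carlo error of the mean estimate `empirical_se / sqrt(R)`.  The
#' signed bias is retained alongside for diagnostics.
#'
#' @param result A [scenario_result()].
#' @return A list of class `"performance_summary"`.
#' @export
summarize_performance <- function(result) {
  stopifnot(inherits(result, "scenario_result"))
  est <- result$estimates
  truth <- result$true_log_or
  signed_bias <- mean(est) - truth
  bias <- abs(signed_bias)
  emp_se <- stats::sd(est)
  structure(list(
    absolute_bias = bias,
    signed_bias = signed_bias,
    relative_bias_pct = 100 * bias / abs(truth),
    empirical_se = emp_se,
    model_based_se = mean(result$ses),
    coverage_pct = 100 * mean(result$ci_low <= truth &
                                truth <= result$ci_high),
    rmse = sqrt(bias^2 + emp_se^2),
    mc_error = emp_se / sqrt(result$n_replicates),
    n_replicates = result$n_replicates
  ), class = "performance_summary")
}
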