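## Scenario-grid orchestration: replicate loop, seed pairing, tidy output.

STUDY_MECHANISMS <- c("MCAR", "MAR_weak", "MAR_strong")
STUDY_PROPORTIONS <- c(0.25, 0.50)
STUDY_TRUE_ORS <- c(1.1, 1.5)
STUDY_METHODS <- c("CCA", "FCS", "MVNI", "TWOFOLD_W1", "TWOFOLD_W2")

#' Configuration of a simulation study
#'
#' @param n_individuals Cohort size per replicate (study default 5000).
#' @param n_replicates Number of replicates per scenario (study default
#'   1000; smaller values use the identical code path).
#' @param true_ors True exposure odds ratios to simulate.
#' @param mechanisms Subset of `"MCAR"`, `"MAR_weak"`, `"MAR_strong"`.
#' @param proportions Subset of final missingness proportions (0.25, 0.50).
#' @param methods Subset of `"CCA"`, `"FCS"`, `"MVNI"`, `"TWOFOLD_W1"`,
#'   `"TWOFOLD_W2"`.
#' @param imputation An [imputation_config()].
#' @param master_seed Master seed; every scenario, replicate and method
#'   receives a derived substream.  Replicate `r` of a scenario gets the
#'   same incomplete dataset whichever methods are enabled, so method
#'   comparisons are paired.
#' @param dropout_share Passed to [missingness_spec()].
#' @return A list of class `"study_config"`.
#' @export
study_config <- function(n_individuals = 5000L, n_replicates = 1000L,
                         true_ors = STUDY_TRUE_ORS,
                         mechanisms = STUDY_MECHANISMS,
                         proportions = STUDY_PROPORTIONS,
                         methods = STUDY_METHODS,
                         imputation = imputation_config(),
                         master_seed = 1L, dropout_share = 0.5) {
  bad <- setdiff(methods, STUDY_METHODS)
  if (length(bad)) stop_invalid("unknown method(s): %s",
                                paste(bad, collapse = ", "))
  bad <- setdiff(mechanisms, STUDY_MECHANISMS)
  if (length(bad)) stop_invalid("unknown mechanism(s): %s",
                                paste(bad, collapse = ", "))
  if (!all(proportions >= 0 & proportions < 1) || !length(proportions)) {
    stop_invalid("proportions must lie in [0, 1)")
  }
  if (n_replicates < 2) stop_invalid("n_replicates must be >= 2")
  if (!length(true_ors) || !length(mechanisms) || !length(methods)) {
    stop_invalid("the scenario grid must be non-empty")
  }
  structure(list(n_individuals = as.integer(n_individuals),
                 n_replicates = as.integer(n_replicates),
                 true_ors = true_ors, mechanisms = mechanisms,
                 proportions = proportions, methods = methods,
                 imputation = imputation,
                 master_seed = as.integer(master_seed),
                 dropout_share = dropout_share),
            class = "study_config")
}

## Canonical scenario index, independent of which subset of the grid is
## being run, so replicate seeds pair across runs.
scenario_index <- function(mechanism, proportion, true_or) {
  im <- match(mechanism, STUDY_MECHANISMS)
  ip <- which.min(abs(STUDY_PROPORTIONS - proportion))
  io <- which.min(abs(STUDY_TRUE_ORS - true_or))
  (io - 1L) * 10L + (ip - 1L) * 5L + im
}

## lambda1 estimate for one method on one masked dataset.
method_estimate <- function(method, pattern, imp, seed) {
  if (method == "CCA") {
    fit <- complete_case_estimate(pattern)
    if (!fit$converged) return(NULL)
    return(list(estimate = fit$beta1, se = fit$se, ci_low = fit$ci_low,
                ci_high = fit$ci_high))
  }
  cs <- switch(method,
    FCS = fcs_impute(pattern, imp, seed = seed),
    MVNI = mvni_impute(pattern, imp, seed = seed),
    TWOFOLD_W1 = {
      imp$window_width <- 1L
      twofold_fcs_impute(pattern, imp, seed = seed)
    },
    TWOFOLD_W2 = {
      imp$window_width <- 2L
      twofold_fcs_impute(pattern, imp, seed = seed)
    },
    stop_invalid("unknown method: %s", method))
  pooled <- pooled_gee_estimate(cs)
  list(estimate = pooled$estimate, se = pooled$se, ci_low = pooled$ci_low,
       ci_high = pooled$ci_high)
}

#' Run one scenario of the simulation study
#'
#' For each replicate: generate a complete cohort, impose missingness, and
#' estimate the exposure log odds ratio with every requested method (MI
#' methods pool `m` imputations by Rubin's rules).  Replicate seeds depend
#' only on the master seed and the canonical scenario index, so all
#' methods see the same incomplete datasets.  Replicates in which a method
#' fails (e.g. non-convergence) are dropped for that method and counted.
#'
#' @param config A [study_config()].
#' @param mechanism,proportion,true_or The scenario cell.
#' @return A list of class `"scenario_run"`: `summaries` (one tidy row per
#'   method with the seven performance measures), `results` (per-replicate
#'   estimates), `failures` (named counts), and the scenario labels.
#' @export
run_scenario <- function(config, mechanism, proportion, true_or) {
  stopifnot(inherits(config, "study_config"))
  dgm <- default_dgm_params(true_or)
  truth <- dgm$followup$lambda1
  spec <- if (proportion > 0) {
    missingness_spec(mechanism, target_final = proportion,
                     dropout_share = config$dropout_share)
  }
  scen <- scenario_index(mechanism, proportion, true_or)
  methods <- config$methods
  rows <- vector("list", config$n_replicates * length(methods))
  failures <- setNames(integer(length(methods)), methods)
  k <- 0L
  for (r in seq_len(config$n_replicates)) {
    rep_seed <- derive_seed(config$master_seed, scen, r)
    panel <- generate_cohort(config$n_individuals, dgm,
                             seed = derive_seed(rep_seed, 1L))
    pattern <- if (!is.null(spec)) {
      apply_missingness(panel, spec, seed = derive_seed(rep_seed, 2L))
    } else {
      structure(list(R = matrix(0L, nrow(panel), N_WAVES), panel = panel,
                     spec = NULL), class = "missingness_pattern")
    }
    for (mi in seq_along(methods)) {
      est <- tryCatch(
        method_estimate(methods[mi], pattern, config$imputation,
                        seed = derive_seed(rep_seed, 10L + match(methods[mi],
                                                                 STUDY_METHODS))),
        error = function(e) NULL)
      if (is.null(est)) {
        failures[mi] <- failures[mi] + 1L
        next
      }
      k <- k + 1L
      rows[[k]] <- data.frame(mechanism = mechanism, proportion = proportion,
                              true_or = true_or, method = methods[mi],
                              replicate = r, estimate = est$estimate,
                              se = est$se, ci_low = est$ci_low,
                              ci_high = est$ci_high)
    }
  }
  results <- do.call(rbind, rows[seq_len(k)])
  summaries <- do.call(rbind, lapply(methods, function(mth) {
    sub <- results[results$method == mth, , drop = FALSE]
    if (nrow(sub) < 2) return(NULL)
    s <- summarize_performance(scenario_result(truth, sub$estimate, sub$se,
                                               sub$ci_low, sub$ci_high))
    data.frame(mechanism = mechanism, proportion = proportion,
               true_or = true_or, method = mth,
               absolute_bias = s$absolute_bias, signed_bias = s$signed_bias,
               relative_bias_pct = s$relative_bias_pct,
               empirical_se = s$empirical_se,
               model_based_se = s$model_based_se,
               coverage_pct = s$coverage_pct, rmse = s$rmse,
               mc_error = s$mc_error, n_replicates = s$n_replicates,
               n_failed = failures[[mth]])
  }))
  structure(list(summaries = summaries, results = results,
                 failures = failures, mechanism = mechanism,
                 proportion = proportion, true_or = true_or,
                 true_log_or = truth),
            class = "scenario_run")
}

#' Run the full scenario grid
#'
#' @param config A [study_config()].
#' @param verbose Print per-scenario progress lines.
#' @return A list of class `"study_run"`: `summaries` and `results` stacked
#'   over the grid, plus a `manifest` (configuration, master seed, package
#'   version, failure counts).
#' @export
run_study <- function(config, verbose = FALSE) {
  grid <- expand.grid(mechanism = config$mechanisms,
                      proportion = config$proportions,
                      true_or = config$true_ors,
                      stringsAsFactors = FALSE)
  runs <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    if (verbose) {
      message(sprintf("scenario %d/%d: %s, %.0f%% missing, OR %.1f",
                      g, nrow(grid), grid$mechanism[g],
                      100 * grid$proportion[g], grid$true_or[g]))
    }
    runs[[g]] <- run_scenario(config, grid$mechanism[g], grid$proportion[g],
                              grid$true_or[g])
  }
  summaries <- do.call(rbind, lapply(runs, `[[`, "summaries"))
  results <- do.call(rbind, lapply(runs, `[[`, "results"))
  manifest <- list(
    package = "longmisim",
    version = as.character(utils::packageVersion("longmisim")),
    master_seed = config$master_seed,
    n_individuals = config$n_individuals,
    n_replicates = config$n_replicates,
    true_ors = config$true_ors, mechanisms = config$mechanisms,
    proportions = config$proportions, methods = config$methods,
    imputation = unclass(config$imputation),
    dropout_share = config$dropout_share,
    failures = lapply(runs, `[[`, "failures")
  )
  structure(list(summaries = summaries, results = results,
                 manifest = manifest),
            class = "study_run")
}

#' Write study outputs
#'
#' Writes `summaries.csv` (one row per scenario x method with the seven
#' performance measures), `replicates.csv` (per-replicate estimates, for
#' audit), and `manifest.json` (configuration, seeds, version, failure
#' counts) under `path`.
#'
#' @param study A `"study_run"` from [run_study()].
#' @param path Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_results <- function(study, path) {
  stopifnot(inherits(study, "study_run"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(path, c("summaries.csv", "replicates.csv",
                             "manifest.json"))
  utils::write.csv(study$summaries, paths[1], row.names = FALSE)
  utils::write.csv(study$results, paths[2], row.names = FALSE)
  jsonlite::write_json(study$manifest, paths[3], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Reshape a summary table into the wide per-scenario layout
#'
#' One block of rows per scenario, with methods as columns and the
#' performance measures as rows, mirroring the conventional presentation
#' of simulation-study results.
#'
#' @param summaries The `summaries` data frame of a `"study_run"`.
#' @return A data frame in wide layout.
#' @export
format_wide_summary <- function(summaries) {
  metrics <- c("absolute_bias", "relative_bias_pct", "empirical_se",
               "model_based_se", "coverage_pct", "rmse")
  scen <- unique(summaries[c("mechanism", "proportion", "true_or")])
  out <- list()
  for (i in seq_len(nrow(scen))) {
    sub <- merge(scen[i, ], summaries)
    block <- data.frame(mechanism = scen$mechanism[i],
                        proportion = scen$proportion[i],
                        true_or = scen$true_or[i],
                        measure = metrics)
    for (mth in unique(sub$method)) {
      block[[mth]] <- vapply(metrics, function(m) {
        sub[sub$method == mth, m][1]
      }, numeric(1))
    }
    out[[i]] <- block
  }
  do.call(rbind, out)
}
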