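# Shared fixtures and memoised expensive objects.  Everything is built in
# code at test time; the cache makes test-file order irrelevant.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, fn) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- fn()
  .fixture_cache[[key]]
}

default_dgm <- function(or = 1.1) {
  memo(paste0("dgm_", or), function() default_dgm_params(or))
}

small_cohort <- function(n = 1000, seed = 7, or = 1.1) {
  memo(sprintf("cohort_%d_%d_%s", n, seed, or),
       function() generate_cohort(n, default_dgm(or), seed = seed))
}

small_pattern <- function(n = 1000, seed = 7, mechanism = "MCAR",
                          prop = 0.25) {
  memo(sprintf("pattern_%d_%d_%s_%s", n, seed, mechanism, prop), function() {
    apply_missingness(small_cohort(n, seed),
                      missingness_spec(mechanism, target_final = prop),
                      seed = seed + 1)
  })
}

# A tiny hand-buildable masked panel wrapper: mask the given (row, wave)
# cells of a cohort panel.
mask_cells <- function(panel, rows, waves) {
  for (k in seq_along(rows)) {
    panel[[paste0("bmiz", waves[k])]][rows[k]] <- NA_real_
  }
  panel
}

# Desk-scale scenario runs shared by the acceptance tests: 60 replicates of
# n = 2500 with m = 5 imputations.  One memoised run per mechanism x
# proportion cell, always with the full method set so every test block can
# reuse the same paired datasets.
acc_scenario <- function(mechanism, prop) {
  memo(sprintf("acc_%s_%s", mechanism, prop), function() {
    methods <- if (prop == 0.25) {
      c("CCA", "FCS", "MVNI", "TWOFOLD_W1", "TWOFOLD_W2")
    } else {
      c("CCA", "FCS", "MVNI", "TWOFOLD_W1")
    }
    cfg <- study_config(n_individuals = 2500, n_replicates = 60,
                        true_ors = 1.1, mechanisms = mechanism,
                        proportions = prop, methods = methods,
                        imputation = imputation_config(m = 5),
                        master_seed = 4242)
    run_scenario(cfg, mechanism, prop, 1.1)
  })
}

acc_summary_grid <- function(prop) {
  do.call(rbind, lapply(c("MCAR", "MAR_weak", "MAR_strong"),
                        function(mech) acc_scenario(mech, prop)$summaries))
}

# Replicate set builder with an exactly specified mean offset and SD, so
# summary arithmetic can be checked against hand values.
exact_result <- function(truth, bias, emp_se, R = 400) {
  z <- scale(seq_len(R))  # mean 0, sd 1 exactly
  est <- truth + bias + emp_se * as.vector(z)
  scenario_result(truth, est, ses = rep(emp_se, R),
                  ci_low = est - 1.96 * emp_se, ci_high = est + 1.96 * emp_se)
}

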