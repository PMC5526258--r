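## Multivariate normal imputation by data augmentation: alternate an
## I-step (draw missing values from their conditional normal) with a
## P-step (draw the mean and covariance from the normal-inverse-Wishart
## posterior under the Jeffreys prior).  The chain itself runs in a
## compiled kernel.

#' Multivariate-normal imputation of a numeric matrix by data augmentation
#'
#' The generic engine behind [mvni_impute()], usable on any numeric matrix
#' with missing entries.  Holes are initialised from the observed margins,
#' then the chain alternates: P-step, draw `Sigma ~ InvWishart(n - 1, S)`
#' (with `S` the centred cross-product of the current completed data) and
#' `mu ~ N(ybar, Sigma / n)`; I-step, redraw each missing block from its
#' conditional normal given the observed entries in the same row.  Rows
#' sharing a missingness pattern are processed together.  One completed
#' matrix is saved every `thin` iterations after `burnin`.
#'
#' If a covariance draw is numerically non positive-definite, a small
#' diagonal jitter is added and the draw retried; persistent failure is an
#' error.
#'
#' @param Y Numeric matrix with `NA` holes; every column needs at least two
#'   observed values and `nrow(Y)` must exceed `ncol(Y)`.
#' @param m Number of saved imputations.
#' @param burnin,thin Chain control.
#' @param seed Integer seed for the whole chain.
#' @return List of `m` completed matrices.
#' @export
mvn_da_impute <- function(Y, m, burnin = 200L, thin = 100L, seed = 1L) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  d <- ncol(Y)
  if (n <= d + 1) stop_invalid("need more rows than columns")
  hole <- is.na(Y)
  if (!any(hole)) return(rep(list(Y), m))
  if (any(colSums(!hole) < 2)) {
    stop_invalid("every column needs at least two observed values")
  }
  pat_key <- apply(hole, 1, function(r) paste(which(r), collapse = ","))
  groups <- split(seq_len(n), pat_key)
  groups <- groups[names(groups) != ""]
  pat_idx <- lapply(groups, function(idx) idx - 1L)
  pat_mc <- lapply(groups, function(idx) which(hole[idx[1], ]) - 1L)

  out <- with_seed(seed, {
    for (v in which(apply(hole, 2, any))) {
      h <- hole[, v]
      Y[h, v] <- sample(Y[!h, v], sum(h), replace = TRUE)
    }
    mvn_da_core(Y, unname(pat_idx), unname(pat_mc),
                as.integer(burnin), as.integer(thin), as.integer(m))
  })
  lapply(out, function(M) {
    dimnames(M) <- dimnames(Y)
    M
  })
}

#' Impute by multivariate normal imputation (MVNI)
#'
#' Fits one joint multivariate normal model over bmiz at all five waves,
#' the sleep-problem indicators at all five waves, and the time-invariant
#' variables (including the auxiliary maternal smoking), by data
#' augmentation.  Binary variables are included under the normality
#' assumption but are never themselves imputed here, since only bmiz at
#' waves 2-5 contains holes.
#'
#' @inheritParams fcs_impute
#' @return A `"completed_set"`.
#' @export
mvni_impute <- function(masked, config = imputation_config(), seed = 1L) {
  panel <- as_masked_panel(masked)
  Z <- as.matrix(panel[IMP_VARS])
  storage.mode(Z) <- "double"
  imputed <- mvn_da_impute(Z, m = config$m, burnin = config$da_burnin,
                           thin = config$da_thin,
                           seed = derive_seed(seed, 500L))
  completed_set(panel, imputed, "MVNI", NULL, seed,
                predictors = list(joint = IMP_VARS))
}
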