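#' Derive a reproducible child seed from a master seed
#'
#' Mixes a master seed with one or more integer indices through two rounds of
#' a multiplicative-congruential step, so that every stage, replicate and
#' imputation of a study receives its own deterministic substream.  All
#' arithmetic stays below 2^53 so the result is exact in double precision,
#' and the returned seed lies in `[1, 2^31 - 2]`.
#'
#' @param master Integer master seed.
#' @param ... Integer indices (stage, scenario, replicate, ...).
#' @return A single integer usable in [set.seed()].
#' @export
derive_seed <- function(master, ...) {
  idx <- c(...)
  m <- 2147483647  # 2^31 - 1 (prime)
  s <- as.numeric(master) %% m
  for (k in seq_along(idx)) {
    s <- (s * 69069 + as.numeric(idx[k]) + k * 97561) %% m
    s <- (s * 69069 + 12345) %% m
  }
  as.integer(s %% (m - 1) + 1)
}

## Evaluate `expr` under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

## rnorm truncated to [lo, hi] via inverse-cdf sampling (vectorised, exact).
rnorm_trunc <- function(n, mean, sd, lo, hi) {
  plo <- pnorm(lo, mean, sd)
  phi <- pnorm(hi, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

## Draw one multivariate-normal deviate per row of `mu` (n x d) with common
## covariance `Sigma` (d x d, PSD; zero rows allowed).
rmvnorm_rows <- function(mu, Sigma) {
  d <- ncol(Sigma)
  ev <- eigen(Sigma, symmetric = TRUE)
  if (min(ev$values) < -1e-8 * max(abs(ev$values), 1)) {
    stop_invalid("covariance matrix is not positive semi-definite")
  }
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), d)
  z <- matrix(rnorm(nrow(mu) * d), nrow(mu), d)
  mu + z %*% t(L)
}

wave_col <- function(prefix, wave) paste0(prefix, wave)

`%||%` <- function(a, b) if (is.null(a)) b else a
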