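# Minimum detectable explained variance for a single-predictor test in a
# covariate-adjusted linear model.

#' Minimum detectable explained variance
#'
#' Solves for the explained variance R^2 at which a 1-df two-sided test of a
#' single predictor reaches the target power at level `alpha`. The default
#' normal approximation uses the required noncentrality
#' `lambda = (z_{1-alpha/2} + z_{power})^2` and `R^2 = lambda / (n + lambda)`.
#' With `exact = TRUE`, the noncentral-F power function
#' (`df1 = 1`, `df2 = n - n_covariates - 2`,
#' `ncp = n R^2 / (1 - R^2)`) is inverted by bisection to 1e-10.
#'
#' @param n sample size (must exceed `n_covariates + 2`).
#' @param alpha two-sided significance level.
#' @param power target power in (0, 1).
#' @param n_covariates number of adjustment covariates (used by the exact
#'   path's denominator degrees of freedom).
#' @param exact use the noncentral-F inversion.
#' @return explained variance in (0, 1).
#' @export
min_detectable_r2 <- function(n, alpha, power = 0.8, n_covariates = 0,
                              exact = FALSE) {
  assert_that(alpha > 0 && alpha < 1, "alpha must be in (0,1)")
  assert_that(power > 0 && power < 1, "power must be in (0,1)")
  assert_that(n > n_covariates + 2, "n must exceed n_covariates + 2")
  if (!exact) {
    lambda <- (qnorm(1 - alpha / 2) + qnorm(power))^2
    r2 <- lambda / (n + lambda)
    assert_that(r2 < 1, "target unattainable: required R^2 >= 1")
    return(r2)
  }
  df2 <- n - n_covariates - 2
  crit <- qf(1 - alpha, 1, df2)
  pow_at <- function(r2) pf(crit, 1, df2, ncp = n * r2 / (1 - r2),
                            lower.tail = FALSE)
  lo <- 1e-12
  hi <- 1 - 1e-12
  assert_that(pow_at(hi) >= power, "target unattainable: required R^2 >= 1")
  while (hi - lo > 1e-10) {
    mid <- (lo + hi) / 2
    if (pow_at(mid) < power) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Bonferroni-corrected significance threshold
#'
#' @param base_alpha nominal level.
#' @param n_tests number of tests (>= 1).
#' @return `base_alpha / n_tests`.
#' @export
bonferroni_alpha <- function(base_alpha, n_tests) {
  assert_that(n_tests >= 1, "n_tests must be >= 1")
  base_alpha / n_tests
}

#' Minimum detectable variance table for several sample sizes
#'
#' @param n_values integer vector of sample sizes.
#' @inheritParams min_detectable_r2
#' @return data frame with `n`, `min_r2`, `min_r2_percent`.
#' @export
power_table <- function(n_values, alpha, power = 0.8, n_covariates = 0,
                        exact = FALSE) {
  r2 <- vapply(n_values, min_detectable_r2, numeric(1), alpha = alpha,
               power = power, n_covariates = n_covariates, exact = exact)
  data.frame(n = n_values, min_r2 = r2, min_r2_percent = 100 * r2)
}
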