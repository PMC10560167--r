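# Per-study probe ~ metabolite association scan.
#
# For each metabolite, every probe is regressed on the metabolite plus the
# shared covariate design (OLS on complete cases). Residual variances are
# shrunk towards a common prior by the empirical-Bayes log-F moment
# estimator, and moderated t-statistics are tested on augmented degrees of
# freedom. Significance is decided by a two-stage (hierarchical)
# Benjamini-Hochberg procedure: BH within each family first, then BH across
# families on each family's smallest adjusted p-value.

#' Per-probe linear associations against one metabolite
#'
#' OLS of every expression column on `metabolite` plus covariates, on the
#' complete cases of metabolite and covariates. Returns the raw residual
#' variances and the unscaled coefficient SE factor needed for moderation.
#'
#' @param expression samples x probes matrix.
#' @param metabolite numeric vector (one metabolite, NAs allowed).
#' @param covariates optional numeric matrix samples x covariates.
#' @return data frame with `probe_id`, `beta`, `se_raw`, `sigma2`,
#'   `df_residual`, `n`; attribute `"stdev_unscaled"` is the common unscaled
#'   SE of the metabolite coefficient.
#' @export
fit_linear_associations <- function(expression, metabolite, covariates = NULL) {
  x <- cbind(`(Intercept)` = 1, metabolite = metabolite, covariates)
  ok <- complete.cases(x)
  x <- x[ok, , drop = FALSE]
  y <- expression[ok, , drop = FALSE]
  assert_that(nrow(x) > ncol(x) + 1, "too few complete cases (%d) for %d predictors",
              nrow(x), ncol(x))
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    bad <- colnames(x)[qx$pivot[(qx$rank + 1):ncol(x)]]
    stop_config("rank-deficient design; collinear column(s): %s",
                paste(bad, collapse = ", "))
  }
  coefs <- qr.coef(qx, y)
  res <- y - x %*% coefs
  df_residual <- nrow(x) - ncol(x)
  sigma2 <- colSums(res^2) / df_residual
  xtx_inv <- chol2inv(qr.R(qx))
  stdev_unscaled <- sqrt(xtx_inv[2, 2])
  out <- data.frame(probe_id = colnames(expression),
                    beta = coefs["metabolite", ],
                    se_raw = stdev_unscaled * sqrt(sigma2),
                    sigma2 = sigma2,
                    df_residual = df_residual,
                    n = nrow(x), row.names = NULL)
  attr(out, "stdev_unscaled") <- stdev_unscaled
  out
}

# Newton inversion of the trigamma function (solve trigamma(x) = y, y > 0)
trigamma_inverse <- function(y) {
  if (y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  x <- 0.5 + 1 / y
  for (i in 1:75) {
    tri <- trigamma(x)
    dif <- (tri - y) / psigamma(x, 2)
    x <- x - dif
    if (x <= 0) x <- .Machine$double.eps
    if (abs(dif) < 1e-10 * x) break
  }
  x
}

#' Empirical-Bayes moderation of residual variances
#'
#' Fits a scaled-F prior `sigma2 ~ s0^2 * F(df, d0)` by matching the mean and
#' variance of `log(sigma2)` to the log-F distribution (digamma/trigamma
#' moment equations, Newton inversion of the trigamma function), then shrinks
#' each variance to its posterior
#' `(d0 * s0^2 + df * sigma2) / (d0 + df)`. When the variances carry no
#' excess dispersion the prior degrees of freedom are infinite and all
#' variances collapse to the common value.
#'
#' @param sigma2 positive residual variances (>= 10 values).
#' @param df_residual residual degrees of freedom (scalar or vector).
#' @return list with `params` (`d0`, `s0_sq`), `s2_post`, and `df_total =
#'   df_residual + d0`.
#' @export
moderate_variances <- function(sigma2, df_residual) {
  assert_that(length(sigma2) >= 10, "need >= 10 probes for moderation")
  df <- rep_len(df_residual, length(sigma2))
  z <- log(pmax(sigma2, 1e-300))
  e <- z - digamma(df / 2) + log(df / 2)
  e_mean <- mean(e)
  e_var <- sum((e - e_mean)^2) / (length(e) - 1)
  rhs <- e_var - mean(trigamma(df / 2))
  if (is.finite(rhs) && rhs > 0) {
    d0 <- 2 * trigamma_inverse(rhs)
    s0_sq <- exp(e_mean + digamma(d0 / 2) - log(d0 / 2))
    s2_post <- (d0 * s0_sq + df * sigma2) / (d0 + df)
  } else {
    d0 <- Inf
    s0_sq <- mean(sigma2)  # degenerate prior: all variances collapse
    s2_post <- rep_len(s0_sq, length(sigma2))
  }
  list(params = list(d0 = d0, s0_sq = s0_sq),
       s2_post = s2_post, df_total = df + d0)
}

#' Moderated t-statistics and association records for one study
#'
#' Runs [fit_linear_associations()] for every metabolite of a prepared study,
#' moderates the residual variances across probes within each metabolite
#' scan, and assembles `AssociationRecord` rows with moderated t, two-sided
#' p, and explained variance `r2 = t^2 / (t^2 + df_total)`.
#'
#' @param prep a `prepared_study` from [preprocess_study()].
#' @param moderated use moderated SEs/t (default) or raw OLS.
#' @return data frame of association records (one row per probe x
#'   metabolite).
#' @export
run_study_associations <- function(prep, moderated = TRUE) {
  assert_that(inherits(prep, "prepared_study"), "prep must be a prepared_study")
  out <- vector("list", ncol(prep$metabolites))
  for (j in seq_len(ncol(prep$metabolites))) {
    fit <- fit_linear_associations(prep$expression, prep$metabolites[, j],
                                   prep$covariates)
    su <- attr(fit, "stdev_unscaled")
    if (moderated && nrow(fit) >= 10) {
      mod <- moderate_variances(fit$sigma2, fit$df_residual)
      se <- su * sqrt(mod$s2_post)
      df_total <- mod$df_total
    } else {
      se <- fit$se_raw
      df_total <- fit$df_residual
    }
    t_stat <- fit$beta / se
    df_eff <- pmin(df_total, 1e9)  # finite df for p/r2 when d0 is infinite
    out[[j]] <- data.frame(study_id = prep$study_id,
                           probe_id = fit$probe_id,
                           metabolite_id = colnames(prep$metabolites)[j],
                           beta = fit$beta, se = se, df = df_eff,
                           t = t_stat,
                           p = 2 * pt(-abs(t_stat), df_eff),
                           n = fit$n,
                           r2 = t_stat^2 / (t_stat^2 + df_eff),
                           row.names = NULL)
  }
  do.call(rbind, out)
}

#' Hierarchical (two-stage) Benjamini-Hochberg adjustment
#'
#' Stage 1: BH within each family (local adjustment). Stage 2: BH across
#' families applied to each family's smallest locally adjusted p-value
#' (global adjustment). A record is significant iff its local adjusted p and
#' its family's global adjusted p are both at or below `q`. The
#' Benjamini-Bogomolov variant additionally scales the local level by the
#' fraction of globally selected families.
#'
#' @param p numeric vector of p-values.
#' @param family family label per p-value (e.g. metabolite for associations,
#'   exposure for mediations).
#' @param q FDR level (default 0.05).
#' @param variant `"conjunction"` (default) or `"bb"`.
#' @return data frame with `p_local_adj`, `p_global_adj`, `significant`.
#' @export
hierarchical_fdr <- function(p, family, q = 0.05, variant = c("conjunction", "bb")) {
  variant <- match.arg(variant)
  assert_that(length(p) == length(family), "p and family must have equal length")
  fam <- as.character(family)
  local <- stats::ave(p, fam, FUN = function(x) p.adjust(x, method = "BH"))
  fam_min <- tapply(local, fam, min)
  global <- p.adjust(fam_min, method = "BH")
  p_global <- as.numeric(global[fam])
  if (variant == "conjunction") {
    significant <- local <= q & p_global <= q
  } else {
    selected <- sum(global <= q)
    q_local <- q * selected / length(fam_min)
    significant <- p_global <= q & local <= q_local
  }
  data.frame(p_local_adj = local, p_global_adj = p_global,
             significant = significant)
}

#' Estimate the proportion of null hypotheses from a p-value collection
#'
#' Storey-style estimator: `eta0(lambda) = #\{p > lambda\} / (m (1 - lambda))`
#' on the grid `lambda = 0, 0.05, ..., 0.9`, smoothed by a cubic smoothing
#' spline with 3 degrees of freedom and evaluated at the largest grid point,
#' clipped to `[0, 1]`.
#'
#' @param p vector of at least 100 p-values.
#' @return list with `eta0` and `eta1 = 1 - eta0`.
#' @export
estimate_eta0 <- function(p) {
  assert_that(length(p) >= 100, "need >= 100 p-values, got %d", length(p))
  lambda <- seq(0, 0.9, by = 0.05)
  eta0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
  fit <- smooth.spline(lambda, eta0_l, df = 3)
  eta0 <- predict(fit, x = max(lambda))$y
  eta0 <- min(max(eta0, 0), 1)
  list(eta0 = eta0, eta1 = 1 - eta0)
}
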