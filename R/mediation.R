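# BMI mediation engine.
#
# For a transcript-metabolite pair the five regressions
#   (1) log-BMI ~ metabolite + covariates
#   (2) log-BMI ~ expression + covariates
#   (3) metabolite ~ expression + covariates
#   (4) expression ~ metabolite + covariates
#   (5) log-BMI ~ metabolite + expression + covariates
# are fitted per study by OLS and pooled by DerSimonian-Laird meta-analysis.
# The mediation effect is the product of coefficients beta_mediation =
# alpha * beta; its p-value compares z_alpha * z_beta with the null
# distribution of the product of two independent standard normal variables
# (density K0(|u|)/pi); confidence intervals come from Monte-Carlo sampling
# of the coefficient distributions; the proportion mediated
# PM = alpha*beta / (alpha*beta + tau') classifies the direction.

# ---------------------------------------------------------------------------
# product-of-two-standard-normals null distribution

#' Density of the product of two independent standard normal variables
#'
#' `f(u) = K0(|u|) / pi` with a logarithmic singularity at 0 (the modified
#' Bessel function of the second kind, order 0).
#'
#' @param u numeric vector (non-zero; the density is infinite at 0).
#' @return density values.
#' @export
prodnorm_density <- function(u) besselK(abs(u), nu = 0) / pi

#' CDF of the product of two independent standard normal variables
#'
#' Computed from the tail integral of `K0(u)/pi` by adaptive quadrature; the
#' log singularity at 0 is avoided entirely by integrating the tail from
#' `|x|` to infinity and using the symmetry `F(x) = 1 - F(-x)`.
#'
#' @param x numeric vector.
#' @return probabilities; `prodnorm_cdf(0) = 0.5` exactly.
#' @export
prodnorm_cdf <- function(x) {
  tail_int <- function(a) {
    if (a > 700) return(0)  # besselK underflows; tail < 1e-300
    stats::integrate(function(u) besselK(u, nu = 0), lower = a, upper = Inf,
                     rel.tol = 1e-12, abs.tol = 1e-14)$value / pi
  }
  vapply(x, function(xi) {
    if (xi == 0) return(0.5)
    tail_prob <- tail_int(abs(xi))
    if (xi > 0) 1 - tail_prob else tail_prob
  }, numeric(1))
}

#' Two-sided mediation p-value from the product of z-statistics
#'
#' `u = z_alpha * z_beta`; `p = 2 * min(F(u), 1 - F(u))` capped at 1, where
#' `F` is [prodnorm_cdf()].
#'
#' @param z_alpha,z_beta z-statistics of the exposure-to-mediator and
#'   mediator-to-outcome effects (vectors recycle).
#' @return p-values.
#' @export
prodnorm_pvalue <- function(z_alpha, z_beta) {
  u <- z_alpha * z_beta
  f <- prodnorm_cdf(u)
  pmin(2 * pmin(f, 1 - f), 1)
}

#' Monte-Carlo confidence interval for a product of coefficients
#'
#' Draws `a ~ N(alpha, se_alpha^2)` and `b ~ N(beta, se_beta^2)`
#' independently and returns empirical quantiles of `a * b`.
#'
#' @param alpha,se_alpha,beta,se_beta coefficient estimates and SEs.
#' @param level central coverage (default 0.95).
#' @param reps number of draws (default 1e5; values below 1e4 warn).
#' @param seed optional integer seed for reproducibility.
#' @return numeric `c(ci_low, ci_high)`.
#' @export
monte_carlo_ci <- function(alpha, se_alpha, beta, se_beta,
                           level = 0.95, reps = 1e5, seed = NULL) {
  assert_that(se_alpha > 0 && se_beta > 0, "SEs must be positive")
  if (reps < 1e4) warning("fewer than 10^4 Monte-Carlo draws; CI will be noisy")
  if (!is.null(seed)) set.seed(seed)
  prod_draws <- rnorm(reps, alpha, se_alpha) * rnorm(reps, beta, se_beta)
  unname(quantile(prod_draws, probs = c((1 - level) / 2, 1 - (1 - level) / 2)))
}

#' Proportion mediated
#'
#' `PM = alpha*beta / (alpha*beta + tau')`, the ratio of the indirect effect
#' to the total effect. Returned unclipped: values outside `[0, 1]` (sign
#' pathologies) are flagged, not altered; a zero total effect yields `NA`
#' with `undefined = TRUE`.
#'
#' @param alpha,beta,tau_prime effect estimates.
#' @return list with `pm`, `out_of_range`, `undefined`.
#' @export
proportion_mediated <- function(alpha, beta, tau_prime) {
  total <- alpha * beta + tau_prime
  if (total == 0) {
    return(list(pm = NA_real_, out_of_range = NA, undefined = TRUE))
  }
  pm <- (alpha * beta) / total
  list(pm = pm, out_of_range = pm < 0 || pm > 1, undefined = FALSE)
}

# ---------------------------------------------------------------------------
# triangle regressions

# OLS coefficient, SE and p of selected terms from lm.fit on complete cases
.ols_terms <- function(y, x, terms) {
  ok <- complete.cases(x) & !is.na(y)
  xo <- x[ok, , drop = FALSE]
  yo <- y[ok]
  qx <- qr(xo)
  if (qx$rank < ncol(xo))
    stop_config("rank-deficient design in triangle regression")
  coefs <- qr.coef(qx, yo)
  res <- yo - drop(xo %*% coefs)
  df <- length(yo) - ncol(xo)
  sigma2 <- sum(res^2) / df
  xtx_inv <- chol2inv(qr.R(qx))
  idx <- match(terms, colnames(xo))
  se <- sqrt(sigma2 * diag(xtx_inv)[idx])
  est <- coefs[idx]
  data.frame(term = terms, beta = est, se = se, df = df,
             p = 2 * pt(-abs(est / se), df), row.names = NULL)
}

#' Meta-pooled triangle regressions for one transcript-metabolite pair
#'
#' Fits the five mediation regressions (and optionally the exposure x
#' mediator interaction model) per study and pools each coefficient over
#' studies by DerSimonian-Laird. Expression is standardised per study and
#' metabolites are INT-standardised by [preprocess_study()]; BMI enters on
#' the log scale.
#'
#' @param probe_id,metabolite_id feature identifiers present in every study.
#' @param studies list of `prepared_study` objects (>= 2 containing the
#'   pair).
#' @param interaction also fit `log-BMI ~ m + g + m:g + covariates`.
#' @return data frame with one row per pooled coefficient: `regression`
#'   (`m_bmi`, `ge_bmi`, `ge_to_m`, `m_to_ge`, `m_cond`, `ge_cond`, and
#'   optionally `interaction`), `beta`, `se`, `z`, `p`, `k`, `Q`, `tau2`,
#'   `i2`.
#' @export
triangle_regressions <- function(probe_id, metabolite_id, studies,
                                 interaction = FALSE) {
  per_study <- list()
  for (prep in studies) {
    if (!(probe_id %in% colnames(prep$expression)) ||
        !(metabolite_id %in% colnames(prep$metabolites))) next
    g <- prep$expression[, probe_id]
    m <- prep$metabolites[, metabolite_id]
    y <- prep$log_bmi
    covs <- prep$covariates
    rows <- rbind(
      cbind(regression = "m_bmi",
            .ols_terms(y, cbind(`(Intercept)` = 1, m = m, covs), "m")),
      cbind(regression = "ge_bmi",
            .ols_terms(y, cbind(`(Intercept)` = 1, g = g, covs), "g")),
      cbind(regression = "ge_to_m",
            .ols_terms(m, cbind(`(Intercept)` = 1, g = g, covs), "g")),
      cbind(regression = "m_to_ge",
            .ols_terms(g, cbind(`(Intercept)` = 1, m = m, covs), "m")),
      {
        both <- .ols_terms(y, cbind(`(Intercept)` = 1, m = m, g = g, covs),
                           c("m", "g"))
        cbind(regression = c("m_cond", "ge_cond"), both)
      })
    if (interaction) {
      rows <- rbind(rows, cbind(regression = "interaction",
        .ols_terms(y, cbind(`(Intercept)` = 1, m = m, g = g, `m:g` = m * g, covs),
                   "m:g")))
    }
    rows$study_id <- prep$study_id
    per_study[[length(per_study) + 1]] <- rows
  }
  assert_that(length(per_study) >= 2,
              "pair %s / %s present in fewer than 2 studies", probe_id, metabolite_id)
  all_rows <- do.call(rbind, per_study)
  pooled <- lapply(split(all_rows, all_rows$regression), function(d) {
    dl <- dersimonian_laird(d$beta, d$se)
    data.frame(regression = d$regression[1], beta = dl$beta, se = dl$se,
               z = dl$z, p = dl$p, k = dl$k, Q = dl$Q, tau2 = dl$tau2,
               i2 = dl$i2, row.names = NULL)
  })
  out <- do.call(rbind, pooled)
  rownames(out) <- NULL
  out$probe_id <- probe_id
  out$metabolite_id <- metabolite_id
  out
}

#' Remove pairs with significant exposure x mediator interaction
#'
#' Fits `log-BMI ~ metabolite + expression + metabolite:expression +
#' covariates` per study, pools the interaction coefficient by
#' DerSimonian-Laird, and removes pairs whose interaction is significant at
#' hierarchical FDR `q` with metabolites as families.
#'
#' @param pairs data frame with columns `probe_id`, `metabolite_id`.
#' @param studies list of `prepared_study`.
#' @param q FDR level.
#' @return list with `retained` (subset of `pairs`) and `records`
#'   (interaction statistics with `removed` flag).
#' @export
interaction_filter <- function(pairs, studies, q = 0.05) {
  if (nrow(pairs) == 0) {
    return(list(retained = pairs,
                records = data.frame(probe_id = character(0),
                                     metabolite_id = character(0))))
  }
  recs <- lapply(seq_len(nrow(pairs)), function(i) {
    tri <- triangle_regressions(pairs$probe_id[i], pairs$metabolite_id[i],
                                studies, interaction = TRUE)
    tri[tri$regression == "interaction", ]
  })
  recs <- do.call(rbind, recs)
  adj <- hierarchical_fdr(recs$p, recs$metabolite_id, q = q)
  recs <- cbind(recs[, c("probe_id", "metabolite_id", "beta", "se", "z", "p", "k")],
                adj)
  recs$removed <- recs$significant
  list(retained = pairs[!recs$removed, , drop = FALSE], records = recs)
}

#' Select testable mediation directions
#'
#' A direction is testable when its exposure has a significant total effect
#' on BMI (`gamma1`) or a significant direct effect (`beta1`, from the joint
#' regression); the latter case is flagged `partial_only`. Pairs qualifying
#' in both directions yield two tests (bi-directional).
#'
#' @param pairs data frame (`probe_id`, `metabolite_id`).
#' @param bmi_flags data frame with columns `probe_id`, `metabolite_id`,
#'   `met_total_sig`, `ge_total_sig`, `met_direct_sig`, `ge_direct_sig`
#'   (per pair).
#' @return data frame of directed tests: `exposure_kind`, `exposure_id`,
#'   `mediator_id`, `probe_id`, `metabolite_id`, `partial_only`,
#'   `bidirectional`.
#' @export
select_testable <- function(pairs, bmi_flags) {
  key <- function(d) paste(d$probe_id, d$metabolite_id, sep = "\r")
  idx <- match(key(pairs), key(bmi_flags))
  assert_that(!anyNA(idx), "every pair needs BMI association flags")
  fl <- bmi_flags[idx, , drop = FALSE]
  met_ok <- fl$met_total_sig | fl$met_direct_sig
  ge_ok <- fl$ge_total_sig | fl$ge_direct_sig
  both <- met_ok & ge_ok
  rows <- list()
  if (any(met_ok)) {
    rows$met <- data.frame(exposure_kind = "metabolite",
                           exposure_id = pairs$metabolite_id[met_ok],
                           mediator_id = pairs$probe_id[met_ok],
                           probe_id = pairs$probe_id[met_ok],
                           metabolite_id = pairs$metabolite_id[met_ok],
                           partial_only = (!fl$met_total_sig & fl$met_direct_sig)[met_ok],
                           bidirectional = both[met_ok])
  }
  if (any(ge_ok)) {
    rows$ge <- data.frame(exposure_kind = "transcript",
                          exposure_id = pairs$probe_id[ge_ok],
                          mediator_id = pairs$metabolite_id[ge_ok],
                          probe_id = pairs$probe_id[ge_ok],
                          metabolite_id = pairs$metabolite_id[ge_ok],
                          partial_only = (!fl$ge_total_sig & fl$ge_direct_sig)[ge_ok],
                          bidirectional = both[ge_ok])
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(exposure_kind = character(0),
                                      exposure_id = character(0),
                                      mediator_id = character(0),
                                      probe_id = character(0),
                                      metabolite_id = character(0),
                                      partial_only = logical(0),
                                      bidirectional = logical(0))
  rownames(out) <- NULL
  out
}

#' Classify a mediation by direction strength
#'
#' A significant mediation with `PM >= pm_cut` whose reverse direction has
#' `PM <= pm_cut` (or is untested) is a strong unidirectional mediation
#' (named for the exposure kind: a strongly mediated metabolite effect when
#' the metabolite is the exposure, a strongly mediated gene expression
#' effect when the transcript is). Significant mediations with `PM >= pm_cut`
#' in both directions are strong bi-directional; remaining significant
#' mediations are weak.
#'
#' @param forward list with `significant`, `pm`, `exposure_kind`.
#' @param reverse optional list with `significant`, `pm` (NULL when the
#'   reverse direction was not tested).
#' @param pm_cut threshold (default 0.2).
#' @return one of `"strong_metabolite_mediated"`, `"strong_ge_mediated"`,
#'   `"strong_bidirectional"`, `"weak"`, `"not_significant"`.
#' @export
classify_mediation <- function(forward, reverse = NULL, pm_cut = 0.2) {
  if (!isTRUE(forward$significant)) return("not_significant")
  fwd_pm <- forward$pm
  rev_sig <- !is.null(reverse) && isTRUE(reverse$significant)
  rev_pm <- if (!is.null(reverse) && is.finite(reverse$pm %||% NA_real_))
    reverse$pm else -Inf  # untested reverse counts as PM <= pm_cut
  if (!is.na(fwd_pm) && fwd_pm >= pm_cut) {
    if (rev_sig && rev_pm >= pm_cut) return("strong_bidirectional")
    if (rev_pm <= pm_cut) {
      return(if (forward$exposure_kind == "metabolite")
        "strong_metabolite_mediated" else "strong_ge_mediated")
    }
  }
  "weak"
}

#' Run the full mediation analysis for a set of directed tests
#'
#' For every directed test, assembles alpha (exposure to mediator), beta
#' (mediator to log-BMI given exposure), tau' (direct effect), gamma1 (total
#' effect) from the pooled triangle regressions, computes the
#' product-of-coefficients statistics, applies hierarchical FDR with
#' exposures as families, Monte-Carlo CIs, the proportion mediated, and the
#' direction classification.
#'
#' @param tests data frame from [select_testable()].
#' @param studies list of `prepared_study`.
#' @param q FDR level.
#' @param pm_cut PM threshold for classification.
#' @param mc_reps Monte-Carlo CI draws.
#' @param seed master seed for the Monte-Carlo CIs.
#' @return data frame of `MediationTriangle` rows.
#' @export
run_mediation <- function(tests, studies, q = 0.05, pm_cut = 0.2,
                          mc_reps = 1e5, seed = 1L) {
  if (nrow(tests) == 0) return(data.frame())
  tri_cache <- new.env(parent = emptyenv())
  get_tri <- function(p, m) {
    k <- paste(p, m, sep = "\r")
    if (is.null(tri_cache[[k]]))
      tri_cache[[k]] <- triangle_regressions(p, m, studies)
    tri_cache[[k]]
  }
  rows <- lapply(seq_len(nrow(tests)), function(i) {
    te <- tests[i, ]
    tri <- get_tri(te$probe_id, te$metabolite_id)
    pick <- function(reg) tri[tri$regression == reg, ]
    if (te$exposure_kind == "metabolite") {
      a <- pick("m_to_ge"); b <- pick("ge_cond")
      tp <- pick("m_cond"); g1 <- pick("m_bmi")
    } else {
      a <- pick("ge_to_m"); b <- pick("m_cond")
      tp <- pick("ge_cond"); g1 <- pick("ge_bmi")
    }
    pm_res <- proportion_mediated(a$beta, b$beta, tp$beta)
    data.frame(exposure_kind = te$exposure_kind,
               exposure_id = te$exposure_id, mediator_id = te$mediator_id,
               probe_id = te$probe_id, metabolite_id = te$metabolite_id,
               alpha = a$beta, se_alpha = a$se,
               beta = b$beta, se_beta = b$se,
               tau_prime = tp$beta, gamma1 = g1$beta,
               z_alpha = a$z, z_beta = b$z,
               beta_mediation = a$beta * b$beta,
               beta_total = a$beta * b$beta + tp$beta,
               pm = pm_res$pm, pm_out_of_range = isTRUE(pm_res$out_of_range),
               p_mediation = prodnorm_pvalue(a$z, b$z),
               partial_only = te$partial_only,
               bidirectional = te$bidirectional,
               row.names = NULL)
  })
  out <- do.call(rbind, rows)
  adj <- hierarchical_fdr(out$p_mediation, out$exposure_id, q = q)
  out <- cbind(out, adj)
  cis <- t(vapply(seq_len(nrow(out)), function(i) {
    monte_carlo_ci(out$alpha[i], out$se_alpha[i], out$beta[i], out$se_beta[i],
                   reps = mc_reps, seed = seed + i)
  }, numeric(2)))
  out$ci_low <- cis[, 1]
  out$ci_high <- cis[, 2]
  out$mc_seed <- seed + seq_len(nrow(out))
  # direction classification needs the reverse record of the same pair
  key <- paste(out$probe_id, out$metabolite_id, sep = "\r")
  out$class <- vapply(seq_len(nrow(out)), function(i) {
    rev_idx <- which(key == key[i] & out$exposure_kind != out$exposure_kind[i])
    reverse <- if (length(rev_idx) == 1)
      list(significant = out$significant[rev_idx], pm = out$pm[rev_idx])
    classify_mediation(list(significant = out$significant[i], pm = out$pm[i],
                            exposure_kind = out$exposure_kind[i]),
                       reverse, pm_cut = pm_cut)
  }, character(1))
  out
}

#' Screen mediations for a gene catalogue
#'
#' Restricts classified mediations to transcripts of the listed genes with a
#' significant mediation and `PM >= pm_cut`, sorted by PM descending.
#'
#' @param mediations data frame from [run_mediation()] with a `gene_symbol`
#'   column, or with `probe_id` resolvable through `probe_map`.
#' @param genes character vector of gene symbols (e.g. a published BMI gene
#'   catalogue, one symbol per line via [readLines()]).
#' @param pm_cut PM threshold (default 0.2).
#' @param probe_map optional data frame (`probe_id`, `gene_symbol`).
#' @return filtered, sorted data frame.
#' @export
screen_gene_catalogue <- function(mediations, genes, pm_cut = 0.2,
                                  probe_map = NULL) {
  if (length(genes) == 0 || nrow(mediations) == 0)
    return(mediations[integer(0), , drop = FALSE])
  if (!("gene_symbol" %in% names(mediations))) {
    assert_that(!is.null(probe_map), "need gene_symbol column or probe_map")
    mediations$gene_symbol <- probe_map$gene_symbol[match(mediations$probe_id,
                                                          probe_map$probe_id)]
  }
  hit <- mediations$gene_symbol %in% genes & mediations$significant &
    !is.na(mediations$pm) & mediations$pm >= pm_cut
  out <- mediations[hit, , drop = FALSE]
  out[order(-out$pm), , drop = FALSE]
}
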