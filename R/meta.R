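# Random-effects meta-analysis of per-study association records.
#
# DerSimonian-Laird pooling with Cochran's Q, the method-of-moments tau^2,
# and I^2 = max(0, (Q - (k-1)) / Q). Pairs present in fewer than two studies
# are excluded from the catalogue.

#' DerSimonian-Laird random-effects pooling of one effect series
#'
#' Fixed-effect weights `w = 1/se^2`; `Q = sum w (b - b_FE)^2`;
#' `tau2 = max(0, (Q - (k-1)) / (sum w - sum w^2 / sum w))`; random-effects
#' weights `w* = 1/(se^2 + tau2)`; pooled effect `sum w* b / sum w*` with
#' `se = (sum w*)^{-1/2}` and a two-sided normal p-value.
#'
#' @param effects numeric vector of study effects (k >= 2).
#' @param ses positive standard errors, same length.
#' @return list with `beta`, `se`, `z`, `p`, `k`, `Q`, `tau2`, `i2`.
#' @export
dersimonian_laird <- function(effects, ses) {
  k <- length(effects)
  assert_that(k >= 2, "need k >= 2 studies, got %d", k)
  assert_that(all(is.finite(ses)) && all(ses > 0), "SEs must be finite and positive")
  w <- 1 / ses^2
  b_fe <- sum(w * effects) / sum(w)
  q <- sum(w * (effects - b_fe)^2)
  c_dl <- sum(w) - sum(w^2) / sum(w)
  tau2 <- if (c_dl > 0) max(0, (q - (k - 1)) / c_dl) else 0
  w_star <- 1 / (ses^2 + tau2)
  beta <- sum(w_star * effects) / sum(w_star)
  se <- 1 / sqrt(sum(w_star))
  z <- beta / se
  i2 <- if (q > 0) max(0, (q - (k - 1)) / q) else 0
  list(beta = beta, se = se, z = z, p = 2 * pnorm(-abs(z)),
       k = k, Q = q, tau2 = tau2, i2 = i2)
}

# vectorised DL over groups defined by a data.table keyed on pair columns
.dl_pool_dt <- function(dt, by_cols) {
  beta <- se <- NULL  # data.table NSE
  dt[, {
    w <- 1 / se^2
    b_fe <- sum(w * beta) / sum(w)
    q <- sum(w * (beta - b_fe)^2)
    c_dl <- sum(w) - sum(w^2) / sum(w)
    tau2 <- if (c_dl > 0) max(0, (q - (.N - 1)) / c_dl) else 0
    w_star <- 1 / (se^2 + tau2)
    bp <- sum(w_star * beta) / sum(w_star)
    sp <- 1 / sqrt(sum(w_star))
    list(beta_pooled = bp, se_pooled = sp, p = 2 * pnorm(-abs(bp / sp)),
         k = .N, Q = q, tau2 = tau2,
         i2 = if (q > 0) max(0, (q - (.N - 1)) / q) else 0,
         mean_r2 = if ("r2" %in% names(dt)) mean(.SD$r2) else NA_real_)
  }, by = by_cols]
}

#' Random-effects meta-analysis catalogue with hierarchical FDR
#'
#' Pools per-study association records (from [run_study_associations()])
#' over studies for every probe x metabolite pair present in at least two
#' studies, applies the hierarchical BH procedure with metabolites as
#' families, and reports the fraction of significant associations with
#' relevant heterogeneity (`I^2 >= 0.75`).
#'
#' @param records data frame with columns `study_id`, `probe_id`,
#'   `metabolite_id`, `beta`, `se` (optionally `r2`).
#' @param q FDR level.
#' @param probe_map optional data frame (`probe_id`, `gene_symbol`) used to
#'   annotate the catalogue.
#' @return data frame of `MetaRecord` rows; attributes `"i2_high_fraction"`
#'   (among significant records) and `"q"`.
#' @export
run_meta_catalog <- function(records, q = 0.05, probe_map = NULL) {
  need <- c("study_id", "probe_id", "metabolite_id", "beta", "se")
  assert_that(all(need %in% names(records)), "records must have columns %s",
              paste(need, collapse = ", "))
  dt <- data.table::as.data.table(records)
  if (anyDuplicated(dt, by = c("study_id", "probe_id", "metabolite_id")))
    stop_config("duplicate (study, probe, metabolite) rows")
  data.table::setkeyv(dt, c("probe_id", "metabolite_id"))
  dt <- dt[, if (.N >= 2) .SD, by = c("probe_id", "metabolite_id")]
  if (nrow(dt) == 0) {
    return(structure(data.frame(), i2_high_fraction = NA_real_, q = q))
  }
  pooled <- .dl_pool_dt(dt, c("probe_id", "metabolite_id"))
  adj <- hierarchical_fdr(pooled$p, pooled$metabolite_id, q = q)
  pooled <- cbind(as.data.frame(pooled), adj)
  if (!is.null(probe_map))
    pooled$gene_symbol <- probe_map$gene_symbol[match(pooled$probe_id,
                                                      probe_map$probe_id)]
  i2_high <- if (any(pooled$significant))
    mean(pooled$i2[pooled$significant] >= 0.75) else NA_real_
  structure(pooled, i2_high_fraction = i2_high, q = q)
}

#' Compare heterogeneity and effects between two catalogues
#'
#' Paired one-sided Wilcoxon signed-rank test of `I^2` (subset smaller than
#' the full analysis) over the pairs shared by both catalogues, and the
#' Pearson correlation of pooled effects over the union of pairs significant
#' in at least one catalogue (or all shared pairs).
#'
#' @param meta_all,meta_subset catalogues from [run_meta_catalog()] sharing
#'   at least 10 pairs.
#' @param effects_on `"significant_union"` (default) or `"all"`.
#' @return list with `wilcoxon_p`, `pearson_r`, `n_shared`.
#' @export
compare_subsets <- function(meta_all, meta_subset,
                            effects_on = c("significant_union", "all")) {
  effects_on <- match.arg(effects_on)
  key <- function(d) paste(d$probe_id, d$metabolite_id, sep = "\r")
  shared <- intersect(key(meta_all), key(meta_subset))
  assert_that(length(shared) >= 10, "catalogues share only %d pairs (need >= 10)",
              length(shared))
  ia <- match(shared, key(meta_all))
  is_ <- match(shared, key(meta_subset))
  d <- meta_subset$i2[is_] - meta_all$i2[ia]
  wilcoxon_p <- if (all(d == 0)) 0.5 else
    suppressWarnings(wilcox.test(meta_subset$i2[is_], meta_all$i2[ia],
                                 paired = TRUE, alternative = "less")$p.value)
  use <- if (effects_on == "significant_union")
    meta_all$significant[ia] | meta_subset$significant[is_] else rep(TRUE, length(ia))
  pearson_r <- if (sum(use) >= 3)
    cor(meta_all$beta_pooled[ia][use], meta_subset$beta_pooled[is_][use]) else NA_real_
  list(wilcoxon_p = wilcoxon_p, pearson_r = pearson_r, n_shared = length(shared))
}
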