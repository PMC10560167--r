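# Study-wise pre-processing.
#
# Metabolites: upper-outlier removal on the log scale -> rank-based inverse
# normal transformation -> empirical-Bayes batch adjustment.
# Expression:  log2 -> quantile normalisation -> empirical-Bayes batch
# adjustment -> probe filters (presence, batch association) -> sample
# distance filter -> probe-to-gene mapping.
# All steps are deterministic, order-explicit and logged in a QC report.

#' Remove extreme upper-tail metabolite measurements
#'
#' Flags measurements whose natural-log value exceeds the mean plus
#' `n_sd` standard deviations of the log-transformed strictly positive
#' values. Zeros (below detection limit) are excluded from the threshold
#' computation and are never flagged.
#'
#' @param values non-negative numeric vector (NAs allowed).
#' @param n_sd threshold multiplier (default 5).
#' @return list with `values` (flagged entries set to `NA`) and `n_removed`.
#' @export
remove_upper_outliers <- function(values, n_sd = 5) {
  assert_that(all(values >= 0, na.rm = TRUE), "values must be non-negative")
  pos <- !is.na(values) & values > 0
  if (sum(pos) < 3) {
    warning("fewer than 3 positive values; upper-outlier removal skipped")
    return(list(values = values, n_removed = 0L))
  }
  lv <- log(values[pos])
  threshold <- mean(lv) + n_sd * sd(lv)
  flag <- pos & log(pmax(values, .Machine$double.xmin)) > threshold
  out <- values
  out[flag] <- NA
  list(values = out, n_removed = sum(flag))
}

#' Rank-based inverse normal transformation
#'
#' Blom scores: `qnorm((rank - 3/8) / (n + 1/4))` computed over the
#' non-missing entries with average ranks for ties; missing values stay
#' missing. Zeros are ranked lowest (retained, not treated as missing).
#'
#' @param values numeric vector with optional NAs.
#' @param offset rank offset (default 3/8, Blom).
#' @return transformed vector, mean approximately 0.
#' @export
inverse_normal_transform <- function(values, offset = 3/8) {
  ok <- !is.na(values)
  assert_that(sum(ok) >= 2, "need >= 2 non-missing values")
  x <- values[ok]
  if (sd(x) == 0) warning("constant vector: inverse normal transform is all zeros")
  r <- rank(x, ties.method = "average")
  out <- values
  out[ok] <- qnorm((r - offset) / (sum(ok) + 1 - 2 * offset))
  out
}

#' Empirical-Bayes batch adjustment
#'
#' Parametric empirical-Bayes location/scale adjustment of a features x
#' samples matrix (ComBat; normal prior on batch means, inverse-gamma prior
#' on batch variances). A single batch is a no-op. Missing values are
#' tolerated feature-wise.
#'
#' @param mat numeric matrix, features in rows, samples in columns.
#' @param batch batch labels, one per sample.
#' @param covariates optional numeric design matrix (samples x covariates)
#'   whose effects are protected during adjustment.
#' @return adjusted matrix of the same dimension.
#' @export
eb_batch_adjust <- function(mat, batch, covariates = NULL) {
  batch <- droplevels(as.factor(batch))
  assert_that(length(batch) == ncol(mat), "one batch label per sample required")
  if (nlevels(batch) < 2) return(mat)
  sizes <- table(batch)
  if (any(sizes < 2))
    stop_config("batch(es) with a single sample: %s",
                paste(names(sizes)[sizes < 2], collapse = ", "))
  mod <- if (!is.null(covariates)) cbind(Intercept = 1, as.matrix(covariates))
  adjusted <- suppressMessages(
    sva::ComBat(dat = mat, batch = batch, mod = mod, par.prior = TRUE))
  dimnames(adjusted) <- dimnames(mat)
  adjusted
}

#' Log2 transformation and quantile normalisation
#'
#' After `log2`, every sample's empirical distribution is replaced by the
#' across-sample mean quantile vector; ties receive the mean of their
#' reference quantiles.
#'
#' @param expression samples x probes matrix of strictly positive intensities.
#' @return normalised samples x probes matrix (log2 scale).
#' @export
log2_quantile_normalize <- function(expression) {
  bad <- which(expression <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop_config("non-positive intensity at [%s]",
                paste(sprintf("%d,%d", bad[1, 1], bad[1, 2]), collapse = "; "))
  normalized <- limma::normalizeQuantiles(t(log2(expression)), ties = TRUE)
  out <- t(normalized)
  dimnames(out) <- dimnames(expression)
  out
}

#' Filter probes by presence and batch association
#'
#' Drops probes expressed (present) in at most `min_rate` of samples, and
#' probes whose one-way ANOVA on batch is Bonferroni-significant
#' (`p <= alpha / n_probes`). When no presence flags are supplied, presence
#' falls back to intensity above the 5th percentile of the study-wide
#' intensity distribution (all probes pooled).
#'
#' @param expression samples x probes matrix (normalised scale).
#' @param presence optional logical samples x probes matrix of detection
#'   flags.
#' @param batch batch labels per sample.
#' @param min_rate presence-rate threshold (default 0.05).
#' @param alpha base level for the Bonferroni batch test (default 0.05).
#' @return list with `kept` (probe names), `report` (data frame of removed
#'   probes and reasons).
#' @export
filter_probes <- function(expression, presence = NULL, batch,
                          min_rate = 0.05, alpha = 0.05) {
  probes <- colnames(expression)
  if (is.null(presence)) {
    presence <- expression > quantile(expression, 0.05)
  }
  assert_that(all(dim(presence) == dim(expression)),
              "presence flags must match the expression matrix")
  rate <- colMeans(presence)
  low <- rate <= min_rate

  batch <- droplevels(as.factor(batch))
  if (nlevels(batch) >= 2) {
    p_batch <- anova_batch_pvalues(expression, batch)
    batchy <- !low & p_batch <= alpha / ncol(expression)
  } else {
    batchy <- rep(FALSE, length(probes))
  }
  report <- rbind(
    data.frame(probe_id = probes[low],
               reason = rep("low_expression", sum(low))),
    data.frame(probe_id = probes[batchy],
               reason = rep("batch_associated", sum(batchy))))
  list(kept = probes[!(low | batchy)], report = report)
}

# vectorised one-way ANOVA F-test of every column on a factor
anova_batch_pvalues <- function(expression, batch) {
  n <- nrow(expression)
  k <- nlevels(batch)
  grand <- colMeans(expression)
  group_sums <- rowsum(expression, batch)
  group_n <- as.vector(table(batch))
  group_means <- group_sums / group_n
  ss_between <- colSums((group_means - rep(grand, each = k))^2 * group_n)
  ss_total <- colSums(sweep(expression, 2, grand)^2)
  ss_within <- pmax(ss_total - ss_between, 0)
  f <- (ss_between / (k - 1)) / (ss_within / (n - k))
  pf(f, k - 1, n - k, lower.tail = FALSE)
}

#' Filter outlying samples by distance from the median sample
#'
#' Computes each sample's Euclidean distance to the feature-wise median
#' sample and removes samples whose distance exceeds
#' `median(distances) + iqr_mult * IQR(distances)` (default rule), or whose
#' distance exceeds `iqr_mult * IQR(distances)` when `rule = "absolute"`.
#'
#' @param expression samples x probes matrix.
#' @param iqr_mult multiplier (default 4).
#' @param rule `"median_plus"` (default) or `"absolute"`.
#' @return list with `kept` (sample names), `report` (removed samples),
#'   `distances`.
#' @export
filter_samples_iqr <- function(expression, iqr_mult = 4,
                               rule = c("median_plus", "absolute")) {
  rule <- match.arg(rule)
  samples <- rownames(expression) %||% as.character(seq_len(nrow(expression)))
  if (nrow(expression) < 8) {
    warning("fewer than 8 samples; sample distance filter skipped")
    return(list(kept = samples, report = data.frame(sample_id = character(0),
                                                    reason = character(0)),
                distances = rep(0, nrow(expression))))
  }
  med <- apply(expression, 2, median)
  d <- sqrt(rowSums(sweep(expression, 2, med)^2))
  iqr <- stats::IQR(d)
  cut <- if (rule == "median_plus") median(d) + iqr_mult * iqr else iqr_mult * iqr
  out <- d > cut
  list(kept = samples[!out],
       report = data.frame(sample_id = samples[out],
                           reason = rep("distance_outlier", sum(out))),
       distances = d)
}

#' Map probes to gene symbols
#'
#' Probes absent from the mapping table are excluded and reported. Several
#' probes may map to the same gene (gene-level de-duplication is deferred to
#' reporting).
#'
#' @param probe_ids character vector.
#' @param probe_map data frame with columns `probe_id`, `gene_symbol` and
#'   unique probe keys.
#' @return list with `mapped` (data frame probe_id, gene_symbol) and
#'   `unmapped` (character vector).
#' @export
map_probes_to_genes <- function(probe_ids, probe_map) {
  assert_that(!anyDuplicated(probe_map$probe_id),
              "duplicate probe keys in mapping table")
  keep <- probe_map[!is.na(probe_map$gene_symbol), , drop = FALSE]
  idx <- match(probe_ids, keep$probe_id)
  unmapped <- probe_ids[is.na(idx)]
  mapped <- data.frame(probe_id = probe_ids[!is.na(idx)],
                       gene_symbol = keep$gene_symbol[idx[!is.na(idx)]])
  list(mapped = mapped, unmapped = unmapped)
}

#' Run the full study-wise pre-processing pipeline
#'
#' Fixed, logged order. Metabolites: upper-outlier removal, inverse normal
#' transformation, empirical-Bayes batch adjustment. Expression: log2 and
#' quantile normalisation, empirical-Bayes batch adjustment, probe presence
#' and batch-association filters, sample distance filter, probe-to-gene
#' mapping. Covariates are carried through; log-BMI is precomputed.
#'
#' @param ds a `study_dataset`.
#' @param quantile_normalize logical; set `FALSE` for data already on a
#'   normalised log2 scale.
#' @param batch_adjust logical; skip empirical-Bayes adjustment entirely
#'   (e.g. single-batch studies are a no-op anyway).
#' @param outlier_sd multiplier for [remove_upper_outliers()].
#' @param presence optional detection flags for [filter_probes()].
#' @return object of class `prepared_study`: standardised expression matrix
#'   (samples x probes), INT metabolite matrix, covariate design (numeric,
#'   standardised), `log_bmi`, `probe_map` of kept probes, and `qc` report.
#' @export
preprocess_study <- function(ds, quantile_normalize = TRUE, batch_adjust = TRUE,
                             outlier_sd = 5, presence = NULL) {
  assert_that(inherits(ds, "study_dataset"), "ds must be a study_dataset")
  steps <- character(0)

  # ---- metabolites ----
  removed_meas <- integer(ncol(ds$metabolites))
  names(removed_meas) <- colnames(ds$metabolites)
  met <- ds$metabolites
  for (j in seq_len(ncol(met))) {
    res <- withCallingHandlers(
      remove_upper_outliers(met[, j], n_sd = outlier_sd),
      warning = function(w) invokeRestart("muffleWarning"))
    met[, j] <- res$values
    removed_meas[j] <- res$n_removed
  }
  steps <- c(steps, "metabolite_upper_outliers")
  met <- apply(met, 2, inverse_normal_transform)
  rownames(met) <- rownames(ds$metabolites)
  steps <- c(steps, "metabolite_inverse_normal_transform")
  if (batch_adjust && nlevels(ds$batch) >= 2) {
    tm <- t(met)
    na_idx <- is.na(tm)
    if (any(na_idx)) {  # EB adjustment needs a complete matrix
      means <- rowMeans(tm, na.rm = TRUE)
      tm[na_idx] <- means[row(tm)[na_idx]]
    }
    tm <- eb_batch_adjust(tm, ds$batch)
    tm[na_idx] <- NA
    met <- t(tm)
    steps <- c(steps, "metabolite_eb_batch_adjust")
  }

  # ---- expression ----
  expr <- if (quantile_normalize) {
    steps <- c(steps, "expression_log2_quantile_normalize")
    log2_quantile_normalize(ds$expression)
  } else {
    assert_that(all(ds$expression > 0), "non-positive expression intensity")
    steps <- c(steps, "expression_log2")
    log2(ds$expression)
  }
  if (batch_adjust && nlevels(ds$batch) >= 2) {
    expr <- t(eb_batch_adjust(t(expr), ds$batch))
    steps <- c(steps, "expression_eb_batch_adjust")
  }
  pf_res <- filter_probes(expr, presence = presence, batch = ds$batch)
  expr <- expr[, pf_res$kept, drop = FALSE]
  steps <- c(steps, "expression_probe_filters")
  sf_res <- suppressWarnings(filter_samples_iqr(expr))
  keep_samples <- sf_res$kept
  steps <- c(steps, "expression_sample_filter")
  map_res <- map_probes_to_genes(colnames(expr), ds$probe_map)
  expr <- expr[, map_res$mapped$probe_id, drop = FALSE]
  steps <- c(steps, "expression_probe_gene_mapping")

  removed_probes <- rbind(
    pf_res$report,
    if (length(map_res$unmapped))
      data.frame(probe_id = map_res$unmapped, reason = "unmapped"))

  idx <- rownames(expr) %in% keep_samples
  covs <- ds$covariates[idx, , drop = FALSE]
  design <- vapply(covs, function(x) zscale(as.numeric(x)), numeric(sum(idx)))
  rownames(design) <- rownames(covs)

  qc <- list(removed_measurements = removed_meas,
             removed_probes = removed_probes,
             removed_samples = sf_res$report,
             parameters = list(outlier_sd = outlier_sd,
                               presence_fallback = is.null(presence),
                               quantile_normalize = quantile_normalize,
                               batch_adjust = batch_adjust),
             steps = steps)

  structure(list(study_id = ds$study_id,
                 expression = scale(expr[idx, , drop = FALSE]),
                 metabolites = met[idx, , drop = FALSE],
                 covariates = design,
                 log_bmi = log(ds$bmi[idx]),
                 batch = ds$batch[idx],
                 probe_map = map_res$mapped,
                 qc = qc),
            class = "prepared_study")
}
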