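# Synthetic multi-study generator with planted mediation triangles.
#
# The generator emulates the design of a multi-cohort blood transcriptome /
# metabolome study: several analysis groups of unequal size, technical batch
# structure, zero-inflated right-skewed metabolite concentrations, shared
# covariate confounding, and a log-normal BMI outcome that is linear in the
# planted exposures and mediators on the log scale.

#' Specify a true mediation triangle
#'
#' A directed exposure -> mediator -> BMI effect chain planted into the
#' synthetic data. Effects are on standardised latent scales: `alpha` is the
#' exposure effect on the mediator, `beta` the mediator effect on log-BMI
#' conditional on the exposure, `tau_prime` the direct exposure effect on
#' log-BMI, and `interaction` an optional exposure x mediator effect on
#' log-BMI (used to exercise the interaction filter).
#'
#' @param exposure_kind `"transcript"` or `"metabolite"`.
#' @param exposure_id,mediator_id feature identifiers; must refer to features
#'   of different kinds.
#' @param alpha,beta,tau_prime,interaction real effect sizes.
#' @return object of class `true_triangle`.
#' @export
true_triangle <- function(exposure_kind = c("transcript", "metabolite"),
                          exposure_id, mediator_id,
                          alpha, beta, tau_prime, interaction = 0) {
  exposure_kind <- match.arg(exposure_kind)
  assert_that(exposure_id != mediator_id, "exposure and mediator must differ")
  structure(list(exposure_kind = exposure_kind,
                 exposure_id = exposure_id, mediator_id = mediator_id,
                 alpha_true = alpha, beta_true = beta,
                 tau_prime_true = tau_prime, interaction_true = interaction),
            class = "true_triangle")
}

#' Simulation configuration
#'
#' Defaults describe the study conditions used throughout the package's own
#' validation: three analysis groups of unequal size, two technical batches
#' per group, modest batch location/scale effects on the log scale, 5%
#' left-censoring of metabolites at the detection limit, six covariates with
#' small effects on log-BMI, mild between-study heterogeneity of true effects,
#' and a log-BMI residual standard deviation of 0.15 (a realistic coefficient
#' of variation for BMI around a median of 27 kg/m^2).
#'
#' @param n_per_study integer vector, samples per analysis group.
#' @param n_probes,n_metabolites feature counts.
#' @param n_batches_per_study batches per group.
#' @param batch_shift_sd,batch_scale_sd SD of additive shifts and of
#'   log multiplicative scale factors per (batch, feature).
#' @param zero_inflation_rate proportion in `[0, 1)` of metabolite values
#'   left-censored to 0 (below detection limit).
#' @param covariate_effect_sizes length-6 vector of covariate effects on
#'   log-BMI (age, sex, fasting_hours, hematocrit, neutrophils, monocytes).
#' @param triangle_specs list of [true_triangle()] objects.
#' @param heterogeneity_sd between-study SD of planted effects.
#' @param noise_sd residual SD of log-BMI.
#' @param seed master integer seed; study `s` uses stream `seed + s`.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(n_per_study = c(1000L, 600L, 350L),
                              n_probes = 100L, n_metabolites = 15L,
                              n_batches_per_study = 2L,
                              batch_shift_sd = 0.3, batch_scale_sd = 0.1,
                              zero_inflation_rate = 0.05,
                              covariate_effect_sizes = c(age = 0.05, sex = -0.03,
                                fasting_hours = -0.02, hematocrit = 0.02,
                                neutrophils = 0.03, monocytes = 0.01),
                              triangle_specs = list(),
                              heterogeneity_sd = 0.02,
                              noise_sd = 0.15,
                              seed = 1L) {
  assert_that(all(n_per_study >= 1) && n_probes >= 1 && n_metabolites >= 1 &&
                n_batches_per_study >= 1, "all sizes must be >= 1")
  assert_that(zero_inflation_rate >= 0 && zero_inflation_rate < 1,
              "zero_inflation_rate must be in [0, 1)")
  assert_that(heterogeneity_sd >= 0, "heterogeneity_sd must be >= 0")
  assert_that(noise_sd > 0, "noise_sd must be > 0")
  assert_that(length(covariate_effect_sizes) == 6,
              "covariate_effect_sizes must have length 6")
  probes <- sprintf("probe_%04d", seq_len(n_probes))
  mets <- sprintf("met_%03d", seq_len(n_metabolites))
  for (tr in triangle_specs) {
    ids <- if (tr$exposure_kind == "transcript") {
      list(expo = probes, medi = mets)
    } else list(expo = mets, medi = probes)
    assert_that(tr$exposure_id %in% ids$expo && tr$mediator_id %in% ids$medi,
                "triangle feature ids must exist and have opposite kinds: %s -> %s",
                tr$exposure_id, tr$mediator_id)
  }
  structure(list(n_per_study = as.integer(n_per_study),
                 n_probes = as.integer(n_probes),
                 n_metabolites = as.integer(n_metabolites),
                 n_batches_per_study = as.integer(n_batches_per_study),
                 batch_shift_sd = batch_shift_sd, batch_scale_sd = batch_scale_sd,
                 zero_inflation_rate = zero_inflation_rate,
                 covariate_effect_sizes = covariate_effect_sizes,
                 triangle_specs = triangle_specs,
                 heterogeneity_sd = heterogeneity_sd,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 probe_ids = probes, metabolite_ids = mets),
            class = "simulation_config")
}

covariate_names <- function() {
  c("age", "sex", "fasting_hours", "hematocrit", "neutrophils", "monocytes")
}

# Fixed structural parameters shared across studies (drawn from the master
# seed): covariate loadings on feature latents (total variance budget 0.1)
# and per-feature location/scale for mapping latents to raw intensities.
.syn_structure <- function(config) {
  set.seed(config$seed)
  n_feat <- config$n_probes + config$n_metabolites
  loadings <- matrix(rnorm(6 * n_feat, sd = sqrt(0.1 / 6)), nrow = 6,
                     dimnames = list(covariate_names(),
                                     c(config$probe_ids, config$metabolite_ids)))
  list(loadings = loadings,
       probe_mu = runif(config$n_probes, 6, 12),
       probe_scale = runif(config$n_probes, 0.3, 1),
       met_mu = runif(config$n_metabolites, 1, 4),
       met_scale = rep(0.6, config$n_metabolites))
}

#' Generate synthetic multi-study data
#'
#' Returns one `study_dataset` per analysis group. Per study, each planted
#' effect is drawn as the triangle effect plus `Normal(0, heterogeneity_sd)`
#' (random-effects heterogeneity). Feature latents have unit marginal
#' variance; metabolites are mapped to a positive log-normal concentration
#' scale and left-censored to zero at the configured rate; expression latents
#' are mapped to positive microarray-like intensities (`2^x`). Batch effects
#' are applied on the log scale per (batch, feature) as an additive shift and
#' a multiplicative scale. BMI is `exp(linear predictor + noise)` so that
#' log-BMI is linear in exposures, mediators and covariates.
#'
#' @param config a [simulation_config()].
#' @return list of `study_dataset` objects; attribute `"truth"` holds the
#'   per-study realised triangle effects.
#' @export
generate_multistudy <- function(config) {
  assert_that(inherits(config, "simulation_config"), "config must be a simulation_config")
  structure_pars <- .syn_structure(config)
  n_studies <- length(config$n_per_study)
  truth <- vector("list", n_studies)
  datasets <- vector("list", n_studies)
  for (s in seq_len(n_studies)) {
    set.seed(config$seed + s)
    datasets[[s]] <- .generate_one_study(config, structure_pars, s)
    truth[[s]] <- attr(datasets[[s]], "study_effects")
  }
  names(datasets) <- vapply(datasets, function(d) d$study_id, character(1))
  attr(datasets, "truth") <- list(config = config, study_effects = truth)
  datasets
}

.generate_one_study <- function(config, sp, s) {
  n <- config$n_per_study[s]
  study_id <- sprintf("study_%d", s)
  samples <- sprintf("%s_s%04d", study_id, seq_len(n))

  covariates <- data.frame(
    age = rnorm(n, 55, 10), sex = rbinom(n, 1, 0.5),
    fasting_hours = pmax(rnorm(n, 8, 3), 0),
    hematocrit = rnorm(n, 42, 3), neutrophils = rnorm(n, 55, 8),
    monocytes = rnorm(n, 8, 2), row.names = samples)
  xs <- vapply(covariates, zscale, numeric(n))
  rownames(xs) <- samples

  batch <- factor(rep_len(sprintf("%s_b%d", study_id, seq_len(config$n_batches_per_study)), n))

  # per-study realised triangle effects (random-effects heterogeneity)
  effects <- lapply(config$triangle_specs, function(tr) {
    tr$alpha_true <- tr$alpha_true + rnorm(1, 0, config$heterogeneity_sd)
    tr$beta_true <- tr$beta_true + rnorm(1, 0, config$heterogeneity_sd)
    tr$tau_prime_true <- tr$tau_prime_true + rnorm(1, 0, config$heterogeneity_sd)
    if (tr$interaction_true != 0)
      tr$interaction_true <- tr$interaction_true + rnorm(1, 0, config$heterogeneity_sd)
    tr
  })

  feat_ids <- c(config$probe_ids, config$metabolite_ids)
  conf_part <- xs %*% sp$loadings  # n x n_feat
  latent <- conf_part + matrix(rnorm(n * length(feat_ids), sd = sqrt(0.9)), nrow = n)
  dimnames(latent) <- list(samples, feat_ids)

  # overwrite mediator latents so that mediator = alpha * exposure + rest,
  # keeping unit marginal variance (exposures stay as drawn: unit variance)
  for (tr in effects) {
    e <- latent[, tr$exposure_id]
    resid_var <- max(1 - tr$alpha_true^2 - 0.1, 0.05)
    latent[, tr$mediator_id] <- tr$alpha_true * e + conf_part[, tr$mediator_id] +
      rnorm(n, sd = sqrt(resid_var))
  }

  log_bmi <- log(27) + drop(xs %*% config$covariate_effect_sizes) +
    rnorm(n, sd = config$noise_sd)
  for (tr in effects) {
    e <- latent[, tr$exposure_id]; m <- latent[, tr$mediator_id]
    log_bmi <- log_bmi + tr$tau_prime_true * e + tr$beta_true * m +
      tr$interaction_true * e * m
  }

  # map latents to observed scales, with batch effects on the log scale
  nb <- config$n_batches_per_study
  shift_probe <- matrix(rnorm(nb * config$n_probes, sd = config$batch_shift_sd), nb)
  scale_probe <- matrix(exp(rnorm(nb * config$n_probes, sd = config$batch_scale_sd)), nb)
  shift_met <- matrix(rnorm(nb * config$n_metabolites, sd = config$batch_shift_sd), nb)
  scale_met <- matrix(exp(rnorm(nb * config$n_metabolites, sd = config$batch_scale_sd)), nb)
  b_idx <- as.integer(batch)

  probe_lat <- latent[, config$probe_ids, drop = FALSE]
  log2_expr <- sweep(sweep(probe_lat * scale_probe[b_idx, , drop = FALSE], 2,
                           sp$probe_scale, `*`) + shift_probe[b_idx, , drop = FALSE],
                     2, sp$probe_mu, `+`)
  expression <- 2^log2_expr

  met_lat <- latent[, config$metabolite_ids, drop = FALSE]
  log_conc <- sweep(sweep(met_lat * scale_met[b_idx, , drop = FALSE], 2,
                          sp$met_scale, `*`) + shift_met[b_idx, , drop = FALSE],
                    2, sp$met_mu, `+`)
  metabolites <- exp(log_conc)
  if (config$zero_inflation_rate > 0) {
    limits <- apply(metabolites, 2, quantile, probs = config$zero_inflation_rate)
    metabolites[sweep(metabolites, 2, limits, `<`)] <- 0
  }

  probe_map <- data.frame(probe_id = config$probe_ids,
                          gene_symbol = sprintf("GENE%04d",
                                                ceiling(seq_len(config$n_probes) / 1.2)))

  ds <- study_dataset(study_id = study_id, expression = expression,
                      metabolites = metabolites, covariates = covariates,
                      bmi = exp(log_bmi), batch = batch, probe_map = probe_map)
  attr(ds, "study_effects") <- effects
  ds
}

#' Construct and validate a study dataset
#'
#' Container for one analysis group's matched data. All components must share
#' the sample index; metabolite values must be non-negative (0 meaning below
#' the detection limit).
#'
#' @param study_id label.
#' @param expression samples x probes matrix of positive intensities.
#' @param metabolites samples x metabolites matrix, non-negative.
#' @param covariates data frame, samples x 6.
#' @param bmi positive numeric vector.
#' @param batch factor (or coercible) per sample.
#' @param probe_map data frame with columns `probe_id`, `gene_symbol`.
#' @return object of class `study_dataset`.
#' @export
study_dataset <- function(study_id, expression, metabolites, covariates,
                          bmi, batch, probe_map) {
  n <- nrow(expression)
  assert_that(nrow(metabolites) == n && nrow(covariates) == n &&
                length(bmi) == n && length(batch) == n,
              "study '%s': all components must share the sample index", study_id)
  assert_that(all(metabolites >= 0, na.rm = TRUE),
              "study '%s': metabolite values must be non-negative", study_id)
  assert_that(all(bmi > 0), "study '%s': BMI must be positive", study_id)
  batch <- droplevels(as.factor(batch))
  assert_that(nlevels(batch) >= 1, "study '%s': batch must have >= 1 level", study_id)
  structure(list(study_id = study_id, expression = expression,
                 metabolites = metabolites, covariates = covariates,
                 bmi = unname(bmi), batch = batch, probe_map = probe_map),
            class = "study_dataset")
}

#' @export
print.study_dataset <- function(x, ...) {
  cat(sprintf("study_dataset '%s': %d samples, %d probes, %d metabolites, %d batches\n",
              x$study_id, nrow(x$expression), ncol(x$expression),
              ncol(x$metabolites), nlevels(x$batch)))
  invisible(x)
}

#' Write a multi-study fixture to disk
#'
#' Per study, four TSV files (expression, metabolites, phenotypes with BMI and
#' batch, probe map) are written, plus one YAML manifest holding the
#' configuration and ground-truth triangles. Numeric values round-trip
#' losslessly through [read_study_fixture()].
#'
#' @param datasets list of `study_dataset` (typically from
#'   [generate_multistudy()]).
#' @param directory output directory (created if needed).
#' @return invisibly, character vector of written paths.
#' @export
write_study_fixture <- function(datasets, directory) {
  assert_that(length(datasets) > 0, "datasets must be non-empty")
  if (!dir.exists(directory)) dir.create(directory, recursive = TRUE)
  assert_that(dir.exists(directory), "cannot create directory '%s'", directory)
  paths <- character(0)
  wr <- function(df, file) {
    path <- file.path(directory, file)
    data.table::fwrite(df, path, sep = "\t")
    path
  }
  mat_df <- function(m) data.frame(sample_id = rownames(m), m,
                                   check.names = FALSE, row.names = NULL)
  for (ds in datasets) {
    id <- ds$study_id
    pheno <- data.frame(sample_id = rownames(ds$expression), ds$covariates,
                        bmi = ds$bmi, batch = as.character(ds$batch),
                        row.names = NULL, check.names = FALSE)
    paths <- c(paths,
               wr(mat_df(ds$expression), paste0(id, "_expression.tsv")),
               wr(mat_df(ds$metabolites), paste0(id, "_metabolites.tsv")),
               wr(pheno, paste0(id, "_phenotypes.tsv")),
               wr(ds$probe_map, paste0(id, "_probe_map.tsv")))
  }
  truth <- attr(datasets, "truth")
  manifest <- list(studies = vapply(datasets, function(d) d$study_id, character(1)),
                   covariates = covariate_names())
  if (!is.null(truth)) {
    cfg <- truth$config
    manifest$config <- cfg[c("n_per_study", "n_probes", "n_metabolites",
                             "n_batches_per_study", "batch_shift_sd", "batch_scale_sd",
                             "zero_inflation_rate", "heterogeneity_sd", "noise_sd", "seed")]
    manifest$config$covariate_effect_sizes <- as.list(cfg$covariate_effect_sizes)
    manifest$triangles <- lapply(cfg$triangle_specs, unclass)
    manifest$study_effects <- lapply(truth$study_effects,
                                     function(trs) lapply(trs, unclass))
  }
  manifest_path <- file.path(directory, "manifest.yaml")
  yaml::write_yaml(manifest, manifest_path, precision = 15)
  invisible(c(paths, manifest_path))
}

#' Read a multi-study fixture written by [write_study_fixture()]
#'
#' @param directory fixture directory containing the TSV files and
#'   `manifest.yaml`. Gzipped TSVs (`.tsv.gz`) are accepted transparently.
#' @return list of `study_dataset`; attribute `"manifest"` holds the parsed
#'   manifest.
#' @export
read_study_fixture <- function(directory) {
  manifest_path <- file.path(directory, "manifest.yaml")
  assert_that(file.exists(manifest_path), "no manifest.yaml in '%s'", directory)
  manifest <- yaml::read_yaml(manifest_path)
  rd <- function(stem) {
    path <- file.path(directory, paste0(stem, ".tsv"))
    if (!file.exists(path)) path <- paste0(path, ".gz")
    assert_that(file.exists(path), "missing fixture file '%s'", path)
    data.table::fread(path, sep = "\t", data.table = FALSE)
  }
  as_mat <- function(df) {
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df$sample_id
    m
  }
  datasets <- lapply(manifest$studies, function(id) {
    pheno <- rd(paste0(id, "_phenotypes"))
    covs <- pheno[, covariate_names(), drop = FALSE]
    rownames(covs) <- pheno$sample_id
    study_dataset(study_id = id,
                  expression = as_mat(rd(paste0(id, "_expression"))),
                  metabolites = as_mat(rd(paste0(id, "_metabolites"))),
                  covariates = covs, bmi = pheno$bmi, batch = pheno$batch,
                  probe_map = rd(paste0(id, "_probe_map")))
  })
  names(datasets) <- manifest$studies
  attr(datasets, "manifest") <- manifest
  datasets
}
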