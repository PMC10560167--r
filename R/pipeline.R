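# Configuration-driven orchestration of the full analysis:
# preprocess -> per-study associations -> random-effects meta-analysis ->
# BMI mediation -> networks -> power table, with all tables, graphs, a QC
# log and a checksummed output manifest written to disk.

#' Pipeline run configuration
#'
#' @param input_dir fixture directory readable by [read_study_fixture()]
#'   (alternatively pass `datasets` to [run_pipeline()] directly).
#' @param output_dir where artifacts are written.
#' @param fdr_level hierarchical FDR level (default 0.05).
#' @param pm_cut proportion-mediated threshold for strong mediations.
#' @param mc_reps Monte-Carlo CI draws.
#' @param seed master seed (recorded in the manifest).
#' @param quantile_normalize passed to [preprocess_study()].
#' @param min_explained_variance association network edge threshold.
#' @param hub_min_degree minimum metabolite degree for hub genes.
#' @param stages named logical vector toggling `assoc`, `mediation`,
#'   `network`, `power`.
#' @return object of class `run_config`.
#' @export
run_config <- function(input_dir = NULL, output_dir = tempfile("metamediate_run_"),
                       fdr_level = 0.05, pm_cut = 0.2, mc_reps = 1e5,
                       seed = 1L, quantile_normalize = TRUE,
                       min_explained_variance = 0.005, hub_min_degree = 2,
                       stages = c(assoc = TRUE, mediation = TRUE,
                                  network = TRUE, power = TRUE)) {
  assert_that(fdr_level > 0 && fdr_level < 1, "fdr_level must be in (0,1)")
  assert_that(pm_cut >= 0 && pm_cut <= 1, "pm_cut must be in [0,1]")
  structure(list(input_dir = input_dir, output_dir = output_dir,
                 fdr_level = fdr_level, pm_cut = pm_cut, mc_reps = mc_reps,
                 seed = as.integer(seed), quantile_normalize = quantile_normalize,
                 min_explained_variance = min_explained_variance,
                 hub_min_degree = hub_min_degree, stages = stages),
            class = "run_config")
}

#' Read a YAML pipeline configuration file
#'
#' @param path YAML file whose keys match the arguments of [run_config()].
#' @return `run_config` object.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$stages)) vals$stages <- unlist(vals$stages)
  do.call(run_config, vals)
}

# feature-level and pair-level BMI association flags needed for mediation
# eligibility; also returns univariate BMI explained variances per feature
.bmi_flags <- function(pairs, studies, q) {
  pool_feature <- function(ids, kind) {
    rows <- lapply(ids, function(id) {
      per <- lapply(studies, function(prep) {
        x <- if (kind == "metabolite") prep$metabolites[, id]
        else prep$expression[, id]
        fit <- .ols_terms(prep$log_bmi, cbind(`(Intercept)` = 1, x = x,
                                              prep$covariates), "x")
        t_stat <- fit$beta / fit$se
        fit$r2 <- t_stat^2 / (t_stat^2 + fit$df)
        fit
      })
      per <- do.call(rbind, per)
      dl <- dersimonian_laird(per$beta, per$se)
      data.frame(feature_id = id, beta = dl$beta, se = dl$se, p = dl$p,
                 r2_bmi = mean(per$r2))
    })
    do.call(rbind, rows)
  }
  mets <- unique(pairs$metabolite_id)
  probes <- unique(pairs$probe_id)
  met_tab <- pool_feature(mets, "metabolite")
  ge_tab <- pool_feature(probes, "transcript")
  met_tab$total_sig <- p.adjust(met_tab$p, "BH") <= q
  ge_tab$total_sig <- p.adjust(ge_tab$p, "BH") <= q

  tri <- lapply(seq_len(nrow(pairs)), function(i)
    triangle_regressions(pairs$probe_id[i], pairs$metabolite_id[i], studies))
  pick <- function(i, reg) tri[[i]][tri[[i]]$regression == reg, "p"]
  m_direct_p <- vapply(seq_along(tri), pick, numeric(1), reg = "m_cond")
  g_direct_p <- vapply(seq_along(tri), pick, numeric(1), reg = "ge_cond")
  m_direct_sig <- hierarchical_fdr(m_direct_p, pairs$metabolite_id, q)$significant
  g_direct_sig <- hierarchical_fdr(g_direct_p, pairs$probe_id, q)$significant

  flags <- data.frame(probe_id = pairs$probe_id,
                      metabolite_id = pairs$metabolite_id,
                      met_total_sig = met_tab$total_sig[match(pairs$metabolite_id,
                                                              met_tab$feature_id)],
                      ge_total_sig = ge_tab$total_sig[match(pairs$probe_id,
                                                            ge_tab$feature_id)],
                      met_direct_sig = m_direct_sig,
                      ge_direct_sig = g_direct_sig)
  node_weights <- rbind(
    data.frame(feature_id = met_tab$feature_id, r2_bmi = met_tab$r2_bmi),
    data.frame(feature_id = ge_tab$feature_id, r2_bmi = ge_tab$r2_bmi))
  list(flags = flags, node_weights = node_weights)
}

#' Run the full pipeline
#'
#' Deterministic given the configuration and seed. Writes per-study QC
#' reports, the per-study association records, the meta-analysis catalogue,
#' the interaction records, the classified mediation table, GraphML/JSON
#' networks, a power table, a run log of all filter counts, and a manifest
#' with MD5 checksums of every artifact.
#'
#' @param config a [run_config()].
#' @param datasets optional list of `study_dataset` (overrides
#'   `config$input_dir`).
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config, datasets = NULL) {
  assert_that(inherits(config, "run_config"), "config must be a run_config")
  set.seed(config$seed)
  if (is.null(datasets)) {
    assert_that(!is.null(config$input_dir), "need input_dir or datasets")
    datasets <- read_study_fixture(config$input_dir)
  }
  out_dir <- config$output_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  artifacts <- character(0)
  log <- list(seed = config$seed, fdr_level = config$fdr_level,
              pm_cut = config$pm_cut,
              studies = vapply(datasets, function(d) d$study_id, character(1)))
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    data.table::fwrite(df, path, sep = "\t")
    artifacts <<- c(artifacts, path)
    path
  }

  # ---- preprocessing ----
  prepared <- lapply(datasets, preprocess_study,
                     quantile_normalize = config$quantile_normalize)
  qc <- lapply(prepared, function(p) p$qc)
  names(qc) <- vapply(prepared, function(p) p$study_id, character(1))
  qc_path <- file.path(out_dir, "qc_report.json")
  jsonlite::write_json(qc, qc_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", force = TRUE)
  artifacts <- c(artifacts, qc_path)
  log$qc <- lapply(qc, function(q) list(
    removed_measurements = sum(q$removed_measurements),
    removed_probes = nrow(q$removed_probes),
    removed_samples = nrow(q$removed_samples)))

  stage_on <- function(s) isTRUE(config$stages[[s]])
  catalogue <- NULL
  mediations <- NULL

  # ---- associations + meta-analysis ----
  if (stage_on("assoc")) {
    records <- do.call(rbind, lapply(prepared, run_study_associations))
    emit(records, "associations_per_study.tsv")
    probe_map <- unique(do.call(rbind, lapply(prepared, function(p) p$probe_map)))
    catalogue <- run_meta_catalog(records, q = config$fdr_level,
                                  probe_map = probe_map)
    emit(catalogue, "meta_catalogue.tsv")
    log$assoc <- list(n_tested = nrow(catalogue),
                      n_significant = sum(catalogue$significant),
                      i2_high_fraction = attr(catalogue, "i2_high_fraction"))
    if (nrow(catalogue) >= 100) {
      eta <- estimate_eta0(catalogue$p)
      log$assoc$eta0 <- eta$eta0
      log$assoc$eta1 <- eta$eta1
    }
  }

  # ---- mediation ----
  if (stage_on("mediation") && !is.null(catalogue)) {
    pairs <- catalogue[catalogue$significant, c("probe_id", "metabolite_id")]
    rownames(pairs) <- NULL
    ifil <- interaction_filter(pairs, prepared, q = config$fdr_level)
    if (nrow(ifil$records) > 0) emit(ifil$records, "interaction_records.tsv")
    log$mediation <- list(pairs_eligible = nrow(pairs),
                          pairs_interaction_removed = nrow(pairs) -
                            nrow(ifil$retained))
    flags <- NULL
    if (nrow(ifil$retained) > 0) {
      fl <- .bmi_flags(ifil$retained, prepared, q = config$fdr_level)
      flags <- fl
      tests <- select_testable(ifil$retained, fl$flags)
      log$mediation$tests_metabolite_exposure <-
        sum(tests$exposure_kind == "metabolite")
      log$mediation$tests_ge_exposure <- sum(tests$exposure_kind == "transcript")
      log$mediation$pairs_bidirectional <- sum(tests$bidirectional) / 2
      if (nrow(tests) > 0) {
        mediations <- run_mediation(tests, prepared, q = config$fdr_level,
                                    pm_cut = config$pm_cut,
                                    mc_reps = config$mc_reps, seed = config$seed)
        probe_map <- unique(do.call(rbind, lapply(prepared, function(p) p$probe_map)))
        mediations$gene_symbol <-
          probe_map$gene_symbol[match(mediations$probe_id, probe_map$probe_id)]
        emit(mediations, "mediations.tsv")
        log$mediation$n_significant <- sum(mediations$significant)
        log$mediation$classes <- as.list(table(mediations$class))
      }
    }
  }

  # ---- networks ----
  if (stage_on("network") && !is.null(catalogue) && any(catalogue$significant)) {
    hubs <- hub_transcripts(catalogue, min_degree = config$hub_min_degree)
    emit(hubs, "hub_transcripts.tsv")
    assoc_net <- association_network(catalogue, hubs = hubs,
                                     min_explained_variance =
                                       config$min_explained_variance)
    p1 <- file.path(out_dir, "association_network.graphml")
    export_graph(assoc_net, p1, "graphml")
    artifacts <- c(artifacts, p1)
    links <- tryCatch(effect_correlation_links(catalogue),
                      error = function(e) NULL)
    if (!is.null(links)) emit(links, "effect_correlation_links.tsv")
    if (!is.null(mediations) && nrow(mediations) > 0) {
      med_net <- mediation_network(mediations, pm_min = 0,
                                   node_weights = if (!is.null(flags))
                                     flags$node_weights)
      p2 <- file.path(out_dir, "mediation_network.graphml")
      export_graph(med_net, p2, "graphml")
      p3 <- file.path(out_dir, "mediation_network.json")
      export_graph(med_net, p3, "json")
      artifacts <- c(artifacts, p2, p3)
    }
    log$network <- list(n_hubs = nrow(hubs))
  }

  # ---- power ----
  if (stage_on("power")) {
    sizes <- vapply(datasets, function(d) nrow(d$expression), numeric(1))
    n_tests <- if (!is.null(catalogue)) max(nrow(catalogue), 1) else 1
    tab <- power_table(c(sort(sizes), sum(sizes)),
                       alpha = bonferroni_alpha(0.05, n_tests))
    emit(tab, "power_table.tsv")
  }

  log_path <- file.path(out_dir, "run_log.json")
  jsonlite::write_json(log, log_path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  artifacts <- c(artifacts, log_path)
  manifest <- list(seed = config$seed,
                   files = data.frame(path = basename(artifacts),
                                      md5 = unname(tools::md5sum(artifacts))))
  manifest_path <- file.path(out_dir, "output_manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(manifest)
}
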