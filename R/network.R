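# Association hub networks, metabolite effect-correlation links, and
# PM-filterable mediation networks, built on igraph with lossless
# GraphML/JSON export.

#' Identify hub transcripts by metabolite degree
#'
#' Degree is the number of unique metabolites significantly associated with
#' a gene, collapsing probes to genes (union of metabolite partners over a
#' gene's probes). Hubs are selected either by a minimum degree or by a top
#' fraction of genes (ties broken by degree, then lexical gene id).
#'
#' @param catalogue data frame from [run_meta_catalog()] with a
#'   `gene_symbol` column.
#' @param min_degree select genes with at least this many metabolites.
#' @param top_fraction select the top fraction of genes by degree.
#' @return data frame with `gene_symbol`, `degree`, sorted by degree
#'   descending.
#' @export
hub_transcripts <- function(catalogue, min_degree = NULL, top_fraction = NULL) {
  assert_that(is.null(min_degree) || is.null(top_fraction),
              "give min_degree or top_fraction, not both")
  sig <- catalogue[catalogue$significant & !is.na(catalogue$gene_symbol), ,
                   drop = FALSE]
  if (nrow(sig) == 0)
    return(data.frame(gene_symbol = character(0), degree = integer(0)))
  deg <- tapply(sig$metabolite_id, sig$gene_symbol,
                function(m) length(unique(m)))
  d <- data.frame(gene_symbol = names(deg), degree = as.integer(deg))
  d <- d[order(-d$degree, d$gene_symbol), , drop = FALSE]
  rownames(d) <- NULL
  if (!is.null(min_degree)) return(d[d$degree >= min_degree, , drop = FALSE])
  if (!is.null(top_fraction)) {
    n_top <- max(1L, floor(top_fraction * nrow(d)))
    return(d[seq_len(min(n_top, nrow(d))), , drop = FALSE])
  }
  d
}

#' Bipartite hub association network
#'
#' Builds a bipartite graph of hub genes and metabolites with one undirected
#' edge per significant association explaining at least
#' `min_explained_variance` of the variance. Edge weight is the explained
#' variance, the sign attribute follows the pooled effect.
#'
#' @param catalogue significant association catalogue with `gene_symbol`,
#'   `metabolite_id`, `mean_r2`, `beta_pooled`.
#' @param hubs optional data frame from [hub_transcripts()]; defaults to all
#'   genes in the catalogue.
#' @param min_explained_variance r2 threshold (default 0.005).
#' @return igraph graph; vertex attributes `kind` ("transcript"/"metabolite")
#'   and `type` (bipartite flag); edge attributes `weight`, `sign`.
#' @export
association_network <- function(catalogue, hubs = NULL,
                                min_explained_variance = 0.005) {
  sig <- catalogue[catalogue$significant, , drop = FALSE]
  if (!is.null(hubs)) sig <- sig[sig$gene_symbol %in% hubs$gene_symbol, ,
                                 drop = FALSE]
  sig <- sig[!is.na(sig$mean_r2) & sig$mean_r2 >= min_explained_variance, ,
             drop = FALSE]
  # collapse probes: keep the best-explained probe per gene x metabolite
  if (nrow(sig) > 0) {
    o <- order(sig$gene_symbol, sig$metabolite_id, -sig$mean_r2)
    sig <- sig[o, , drop = FALSE]
    sig <- sig[!duplicated(sig[, c("gene_symbol", "metabolite_id")]), ,
               drop = FALSE]
  }
  genes <- unique(sig$gene_symbol)
  mets <- unique(sig$metabolite_id)
  g <- igraph::make_empty_graph(directed = FALSE)
  g <- igraph::add_vertices(g, length(genes), name = genes, kind = "transcript",
                            type = TRUE)
  g <- igraph::add_vertices(g, length(mets), name = mets, kind = "metabolite",
                            type = FALSE)
  if (nrow(sig) > 0) {
    g <- igraph::add_edges(g, rbind(sig$gene_symbol, sig$metabolite_id),
                           weight = sig$mean_r2,
                           sign = ifelse(sig$beta_pooled >= 0, 1, -1))
  }
  g
}

#' Metabolite-metabolite effect-correlation links
#'
#' Pearson correlation of the standardised pooled effect estimates of two
#' metabolites over their shared tested transcripts; pairs sharing fewer
#' than `min_shared` transcripts are skipped. Links with `|r| >= threshold`
#' are reported with their sign.
#'
#' @param catalogue meta-analysis catalogue (`probe_id`, `metabolite_id`,
#'   `beta_pooled`, `significant`).
#' @param threshold absolute correlation cutoff (default 0.9).
#' @param min_shared minimum shared transcripts (default 10).
#' @param significant_only correlate over significant associations only.
#' @return data frame with `metabolite_a`, `metabolite_b`, `r`, `sign`,
#'   `n_shared`.
#' @export
effect_correlation_links <- function(catalogue, threshold = 0.9,
                                     min_shared = 10, significant_only = FALSE) {
  cat_use <- if (significant_only)
    catalogue[catalogue$significant, , drop = FALSE] else catalogue
  mets <- unique(cat_use$metabolite_id)
  assert_that(length(mets) >= 2, "need >= 2 metabolites")
  eff <- tapply(cat_use$beta_pooled,
                list(cat_use$probe_id, cat_use$metabolite_id), identity)
  links <- list()
  for (i in seq_along(mets)) {
    for (j in seq_along(mets)) {
      if (j <= i) next
      a <- eff[, mets[i]]
      b <- eff[, mets[j]]
      ok <- !is.na(a) & !is.na(b)
      if (sum(ok) < min_shared) next
      r <- cor(a[ok], b[ok])
      if (is.na(r) || abs(r) < threshold) next
      links[[length(links) + 1]] <- data.frame(
        metabolite_a = mets[i], metabolite_b = mets[j], r = r,
        sign = ifelse(r >= 0, 1, -1), n_shared = sum(ok))
    }
  }
  if (length(links) == 0)
    return(data.frame(metabolite_a = character(0), metabolite_b = character(0),
                      r = numeric(0), sign = numeric(0), n_shared = integer(0)))
  do.call(rbind, links)
}

#' Directed mediation network
#'
#' One directed edge per significant mediation with `PM >= pm_min`, from
#' exposure to mediator. Edge attributes carry the mediation effect, PM and
#' classification; node weights are the univariate explained variance of
#' BMI (`r2` of the total-effect regression) when supplied.
#'
#' @param mediations classified table from [run_mediation()].
#' @param pm_min minimum proportion mediated (default 0).
#' @param nodes_filter optional character vector of feature ids; edges are
#'   restricted to triangles touching these nodes.
#' @param node_weights optional data frame (`feature_id`, `r2_bmi`).
#' @return directed igraph graph.
#' @export
mediation_network <- function(mediations, pm_min = 0, nodes_filter = NULL,
                              node_weights = NULL) {
  ed <- mediations[mediations$significant & !is.na(mediations$pm) &
                     mediations$pm >= pm_min, , drop = FALSE]
  if (!is.null(nodes_filter)) {
    ed <- ed[ed$exposure_id %in% nodes_filter |
               ed$mediator_id %in% nodes_filter, , drop = FALSE]
  }
  nodes <- unique(c(ed$exposure_id, ed$mediator_id))
  kinds <- ifelse(nodes %in% c(ed$probe_id, mediations$probe_id),
                  "transcript", "metabolite")
  g <- igraph::make_empty_graph(directed = TRUE)
  g <- igraph::add_vertices(g, length(nodes), name = nodes, kind = kinds)
  if (!is.null(node_weights) && length(nodes) > 0) {
    w <- node_weights$r2_bmi[match(nodes, node_weights$feature_id)]
    g <- igraph::set_vertex_attr(g, "weight", value = ifelse(is.na(w), 0, w))
  }
  if (nrow(ed) > 0) {
    g <- igraph::add_edges(g, rbind(ed$exposure_id, ed$mediator_id),
                           weight = ed$beta_mediation, pm = ed$pm,
                           sign = ifelse(ed$beta_mediation >= 0, 1, -1),
                           class = ed$class,
                           kind = ifelse(ed$exposure_kind == "metabolite",
                                         "mediation_forward", "mediation_reverse"))
  }
  g
}

#' Export a graph to GraphML or JSON node-link format
#'
#' All node and edge attributes round-trip losslessly through
#' [import_graph()].
#'
#' @param graph igraph graph.
#' @param path output file.
#' @param format `"graphml"` or `"json"`.
#' @return invisibly, `path`.
#' @export
export_graph <- function(graph, path, format = c("graphml", "json")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(graph, path, format = "graphml")
  } else {
    va <- igraph::vertex_attr(graph)
    nodes <- if (length(va)) as.data.frame(va, stringsAsFactors = FALSE) else
      data.frame()
    ea <- igraph::edge_attr(graph)
    el <- igraph::as_edgelist(graph)
    edges <- data.frame(source = el[, 1], target = el[, 2])
    for (nm in names(ea)) edges[[nm]] <- ea[[nm]]
    jsonlite::write_json(list(directed = igraph::is_directed(graph),
                              nodes = nodes, links = edges),
                         path, auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

#' Import a graph written by [export_graph()]
#'
#' @param path file path.
#' @param format `"graphml"` or `"json"`.
#' @return igraph graph.
#' @export
import_graph <- function(path, format = c("graphml", "json")) {
  format <- match.arg(format)
  if (format == "graphml") return(igraph::read_graph(path, format = "graphml"))
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  nodes <- as.data.frame(doc$nodes)
  g <- igraph::make_empty_graph(directed = isTRUE(doc$directed))
  if (nrow(nodes) > 0) {
    g <- igraph::add_vertices(g, nrow(nodes))
    for (nm in names(nodes)) g <- igraph::set_vertex_attr(g, nm, value = nodes[[nm]])
  }
  links <- as.data.frame(doc$links)
  if (nrow(links) > 0) {
    g <- igraph::add_edges(g, rbind(links$source, links$target))
    for (nm in setdiff(names(links), c("source", "target")))
      g <- igraph::set_edge_attr(g, nm, value = links[[nm]])
  }
  g
}
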