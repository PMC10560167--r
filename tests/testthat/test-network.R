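# minimal significant catalogue for network construction
toy_catalogue <- function() {
  data.frame(
    probe_id = c("p1", "p2", "p3", "p4", "p5"),
    metabolite_id = c("m1", "m1", "m2", "m2", "m1"),
    gene_symbol = c("G1", "G1", "G2", "G3", "G3"),
    beta_pooled = c(0.5, 0.4, -0.3, 0.2, 0.1),
    mean_r2 = c(0.02, 0.01, 0.006, 0.004, 0.008),
    significant = c(TRUE, TRUE, TRUE, TRUE, FALSE))
}

test_that("hub selection collapses probes to genes with union degree", {
  cat_ <- rbind(toy_catalogue(),
                data.frame(probe_id = "p2b", metabolite_id = "m2",
                           gene_symbol = "G1", beta_pooled = 0.2,
                           mean_r2 = 0.01, significant = TRUE))
  hubs <- hub_transcripts(cat_)
  expect_equal(hubs$degree[hubs$gene_symbol == "G1"], 2)  # m1 + m2 across probes
  expect_equal(hub_transcripts(cat_, min_degree = 2)$gene_symbol, "G1")
  top <- hub_transcripts(cat_, top_fraction = 0.34)
  expect_equal(top$gene_symbol, "G1")
  expect_error(hub_transcripts(cat_, min_degree = 1, top_fraction = 0.5), "not both")
  empty <- toy_catalogue()
  empty$significant <- FALSE
  expect_equal(nrow(hub_transcripts(empty)), 0)
})

test_that("association network is bipartite and threshold-filtered", {
  g <- association_network(toy_catalogue(), min_explained_variance = 0.005)
  expect_true(igraph::is_bipartite(g))
  # p4 (r2 = 0.004) and p5 (not significant) are excluded; p1 and p2 share
  # gene G1 and metabolite m1, so they collapse to a single edge
  expect_equal(igraph::ecount(g), 2)
  edge_sign <- igraph::E(g)$sign[igraph::get_edge_ids(g, c("G2", "m2"))]
  expect_equal(edge_sign, -1)
  # every edge joins a transcript and a metabolite
  ends <- igraph::as_edgelist(g)
  kinds <- igraph::V(g)$kind[match(ends, igraph::V(g)$name)]
  kinds <- matrix(kinds, ncol = 2)
  expect_true(all(kinds[, 1] != kinds[, 2]))
  # lowering the threshold only adds edges; all significant gene-metabolite
  # pairs (G1-m1, G2-m2, G3-m2) appear when nothing is filtered
  g_all <- association_network(toy_catalogue(), min_explained_variance = 0)
  expect_gte(igraph::ecount(g_all), igraph::ecount(g))
  expect_equal(igraph::ecount(g_all), 3)
})

test_that("effect correlation links find duplicated metabolites and skip noise", {
  set.seed(7)
  base <- rnorm(30)
  cat_ <- rbind(
    data.frame(probe_id = sprintf("p%02d", 1:30), metabolite_id = "mA",
               beta_pooled = base, significant = TRUE),
    data.frame(probe_id = sprintf("p%02d", 1:30), metabolite_id = "mA_copy",
               beta_pooled = base, significant = TRUE),
    data.frame(probe_id = sprintf("p%02d", 1:30), metabolite_id = "mNeg",
               beta_pooled = -0.98 * base + rnorm(30, 0, 0.01), significant = TRUE))
  links <- effect_correlation_links(cat_, threshold = 0.9)
  key <- paste(links$metabolite_a, links$metabolite_b)
  expect_true("mA mA_copy" %in% key)
  expect_equal(links$r[key == "mA mA_copy"], 1)
  expect_equal(links$sign[key == "mA mNeg"], -1)

  # independent effect vectors essentially never reach |r| >= 0.9
  set.seed(8)
  cat_null <- do.call(rbind, lapply(c("x", "y", "z"), function(m)
    data.frame(probe_id = sprintf("p%04d", 1:1000), metabolite_id = m,
               beta_pooled = rnorm(1000), significant = TRUE)))
  expect_equal(nrow(effect_correlation_links(cat_null, threshold = 0.9)), 0)

  # too few shared transcripts: pair skipped
  expect_equal(nrow(effect_correlation_links(cat_[c(1:5, 31:35), ])), 0)
})

test_that("mediation network filters by PM and restricts to requested nodes", {
  med <- data.frame(
    exposure_kind = c("metabolite", "transcript", "metabolite"),
    exposure_id = c("m1", "p1", "m2"),
    mediator_id = c("p1", "m1", "p2"),
    probe_id = c("p1", "p1", "p2"),
    metabolite_id = c("m1", "m1", "m2"),
    beta_mediation = c(0.02, -0.01, 0.005),
    pm = c(0.25, 0.1, 0.4),
    significant = c(TRUE, TRUE, TRUE),
    class = c("strong_metabolite_mediated", "weak", "weak"))
  g <- mediation_network(med, pm_min = 0.2)
  expect_true(igraph::is_directed(g))
  expect_equal(igraph::ecount(g), 2)
  g_all <- mediation_network(med, pm_min = 0)
  expect_equal(igraph::ecount(g_all), sum(med$significant))
  g_m2 <- mediation_network(med, pm_min = 0, nodes_filter = "m2")
  expect_equal(igraph::ecount(g_m2), 1)
  # edge-count monotone in the PM threshold
  counts <- vapply(c(0, 0.1, 0.25, 0.41),
                   function(t) igraph::ecount(mediation_network(med, t)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("graph export round-trips through GraphML and JSON", {
  med <- data.frame(
    exposure_kind = "metabolite", exposure_id = "m1", mediator_id = "p1",
    probe_id = "p1", metabolite_id = "m1", beta_mediation = 0.02,
    pm = 0.25, significant = TRUE, class = "strong_metabolite_mediated")
  g <- mediation_network(med, pm_min = 0,
                         node_weights = data.frame(feature_id = c("m1", "p1"),
                                                   r2_bmi = c(0.01, 0.002)))
  for (fmt in c("graphml", "json")) {
    path <- tempfile(fileext = paste0(".", fmt))
    export_graph(g, path, fmt)
    g2 <- import_graph(path, fmt)
    expect_equal(igraph::vcount(g2), igraph::vcount(g))
    expect_equal(igraph::ecount(g2), igraph::ecount(g))
    expect_setequal(igraph::V(g2)$name, igraph::V(g)$name)
    expect_equal(sort(igraph::V(g2)$weight), sort(igraph::V(g)$weight))
    expect_equal(igraph::E(g2)$pm, igraph::E(g)$pm)
    expect_equal(igraph::E(g2)$class, igraph::E(g)$class)
    expect_equal(igraph::is_directed(g2), igraph::is_directed(g))
  }
  # empty graph still produces a valid readable document
  g0 <- mediation_network(med[0, ], pm_min = 0)
  for (fmt in c("graphml", "json")) {
    path <- tempfile(fileext = paste0(".", fmt))
    export_graph(g0, path, fmt)
    expect_equal(igraph::vcount(import_graph(path, fmt)), 0)
  }
  expect_error(export_graph(g, tempfile(), "dot"), "arg")
})
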