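# Shared fixture builders (all data generated in code).

# small three-study design with two planted triangles, one per direction
small_multistudy <- function(seed = 42, n = 300, n_probes = 30, n_mets = 6) {
  cfg <- simulation_config(
    n_per_study = rep(n, 3), n_probes = n_probes, n_metabolites = n_mets,
    triangle_specs = list(
      true_triangle("transcript", "probe_0001", "met_001", 0.5, 0.2, 0.1),
      true_triangle("metabolite", "met_002", "probe_0002", 0.5, 0.2, 0.1)),
    seed = seed)
  generate_multistudy(cfg)
}

# brute-force Benjamini-Hochberg oracle: sort, m*p/i, cumulative minimum
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- m * p[o] / seq_len(m)
  adj <- pmin(rev(cummin(rev(q))), 1)
  out <- numeric(m)
  out[o] <- adj
  out
}
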