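test_that("product-normal CDF has the exact symmetry and limits", {
  expect_equal(prodnorm_cdf(0), 0.5)
  x <- c(0.1, 0.5, 1, 2, 4, 10)
  expect_lt(max(abs(prodnorm_cdf(x) + prodnorm_cdf(-x) - 1)), 1e-10)
  expect_true(all(diff(prodnorm_cdf(c(-5, -1, -0.1, 0, 0.1, 1, 5))) > 0))
  expect_equal(prodnorm_cdf(50), 1, tolerance = 1e-10)
  expect_equal(prodnorm_cdf(1e6), 1, tolerance = 1e-12)
})

test_that("product-normal density integrates to one", {
  total <- 2 * stats::integrate(prodnorm_density, 0, Inf,
                                rel.tol = 1e-12)$value
  expect_equal(total, 1, tolerance = 1e-8)
})

test_that("product-normal p-values follow the two-sided product rule", {
  expect_equal(prodnorm_pvalue(0, 5), 1)
  p22 <- prodnorm_pvalue(2, 2)
  expect_equal(p22, 2 * (1 - prodnorm_cdf(4)), tolerance = 1e-12)
  # sign flips of either z leave the two-sided p unchanged
  expect_equal(prodnorm_pvalue(-2, 2), p22, tolerance = 1e-12)
  expect_equal(prodnorm_pvalue(2, -2), p22, tolerance = 1e-12)
  expect_true(all(prodnorm_pvalue(c(-3, 0.5, 8), c(1, 1, 8)) <= 1))
})

test_that("product test is calibrated (conservative) under the null", {
  rate <- prodnorm_null_calibration(n_triangles = 1e4, level = 0.05, seed = 5)
  expect_lte(rate, 0.06)
  expect_gte(rate, 0.03)
})

test_that("Monte-Carlo CI brackets the product and matches a larger oracle", {
  ci0 <- monte_carlo_ci(0, 1, 0, 1, reps = 2e5, seed = 1)
  expect_lt(abs(ci0[1] + ci0[2]), 0.05)  # symmetric about 0

  ci15 <- monte_carlo_ci(5, 0.01, 3, 0.01, reps = 1e5, seed = 2)
  expect_lt(abs(ci15[1] - 15), 0.2)
  expect_lt(abs(ci15[2] - 15), 0.2)

  ci <- monte_carlo_ci(0.3, 0.05, 0.2, 0.05, reps = 1e5, seed = 3)
  set.seed(1234)
  oracle <- quantile(rnorm(1e7, 0.3, 0.05) * rnorm(1e7, 0.2, 0.05),
                     c(0.025, 0.975))
  # MC SE of a quantile estimate at 1e5 draws
  mc_se <- 0.0004
  expect_lt(abs(ci[1] - oracle[1]), 3 * mc_se)
  expect_lt(abs(ci[2] - oracle[2]), 3 * mc_se)

  expect_warning(monte_carlo_ci(1, 1, 1, 1, reps = 100, seed = 1), "10\\^4")
  # seeded: reproducible
  expect_identical(monte_carlo_ci(1, 1, 1, 1, seed = 9),
                   monte_carlo_ci(1, 1, 1, 1, seed = 9))
})

test_that("proportion mediated follows the indirect/total ratio", {
  # printed-style worked case: mediation -0.003 of a -0.0072 total
  pm <- proportion_mediated(-0.003, 1, -0.0072 + 0.003)
  expect_equal(round(pm$pm, 2), 0.42)
  expect_equal(proportion_mediated(0.3, 0.2, 0)$pm, 1)       # tau' = 0
  expect_equal(proportion_mediated(0.2, 0.3, 0.06)$pm, 0.5)  # ab = tau'
  neg <- proportion_mediated(0.5, 0.4, -0.1)
  expect_gt(neg$pm, 1)
  expect_true(neg$out_of_range)
  und <- proportion_mediated(0.5, 0.4, -0.2)
  expect_true(und$undefined)
  expect_true(is.na(und$pm))
})

test_that("mediation classification implements the PM direction rules", {
  fwd <- function(pm, kind = "metabolite", sig = TRUE)
    list(significant = sig, pm = pm, exposure_kind = kind)
  rev_ <- function(pm, sig = TRUE) list(significant = sig, pm = pm)

  expect_equal(classify_mediation(fwd(0.25), rev_(0.05)),
               "strong_metabolite_mediated")
  expect_equal(classify_mediation(fwd(0.25, "transcript"), rev_(0.05)),
               "strong_ge_mediated")
  expect_equal(classify_mediation(fwd(0.3), rev_(0.25)), "strong_bidirectional")
  expect_equal(classify_mediation(fwd(0.05), rev_(0.1)), "weak")
  expect_equal(classify_mediation(fwd(0.25, sig = FALSE), rev_(0.05)),
               "not_significant")
  # untested reverse counts as PM <= cutoff
  expect_equal(classify_mediation(fwd(0.25)), "strong_metabolite_mediated")
  # reverse above cutoff but not significant blocks strong, gives weak
  expect_equal(classify_mediation(fwd(0.25), rev_(0.3, sig = FALSE)), "weak")
})

test_that("testable directions follow total/direct BMI significance", {
  pairs <- data.frame(probe_id = c("p1", "p2", "p3", "p4"),
                      metabolite_id = c("m1", "m2", "m3", "m4"))
  flags <- data.frame(pairs,
                      met_total_sig = c(TRUE, FALSE, TRUE, FALSE),
                      ge_total_sig = c(FALSE, TRUE, TRUE, FALSE),
                      met_direct_sig = c(FALSE, FALSE, FALSE, FALSE),
                      ge_direct_sig = c(FALSE, FALSE, FALSE, TRUE))
  tests <- select_testable(pairs, flags)
  # p1/m1: metabolite exposure only; p2/m2: transcript only;
  # p3/m3: both (bi-directional); p4/m4: transcript via direct effect only
  expect_equal(sum(tests$exposure_kind == "metabolite"), 2)
  expect_equal(sum(tests$exposure_kind == "transcript"), 3)
  expect_equal(sum(tests$bidirectional), 2)
  expect_true(tests$partial_only[tests$probe_id == "p4"])
  expect_equal(nrow(select_testable(pairs[0, ], flags)), 0)
})

test_that("triangle regressions recover planted effects and the effect decomposition", {
  cfg <- simulation_config(n_per_study = c(1000, 1000, 1000), n_probes = 4,
                           n_metabolites = 4,
                           triangle_specs = list(
                             true_triangle("transcript", "probe_0001", "met_001",
                                           0.3, 0.2, 0.1)),
                           heterogeneity_sd = 0, seed = 91)
  prepared <- lapply(generate_multistudy(cfg), preprocess_study,
                     quantile_normalize = FALSE)
  tri <- triangle_regressions("probe_0001", "met_001", prepared)
  pick <- function(reg) tri[tri$regression == reg, ]
  expect_lt(abs(pick("ge_to_m")$beta - 0.3), 3 * pick("ge_to_m")$se)
  expect_lt(abs(pick("m_cond")$beta - 0.2), 3 * pick("m_cond")$se)
  expect_lt(abs(pick("ge_cond")$beta - 0.1), 3 * pick("ge_cond")$se)
  # total = direct + indirect for linear models
  indirect <- pick("ge_to_m")$beta * pick("m_cond")$beta
  expect_lt(abs(pick("ge_bmi")$beta - (pick("ge_cond")$beta + indirect)),
            3 * pick("ge_bmi")$se)
  # a feature with no planted BMI effect stays near zero
  tri_null <- triangle_regressions("probe_0003", "met_003", prepared)
  expect_true(all(abs(tri_null$beta) < 3 * tri_null$se + 1e-9))
  expect_error(triangle_regressions("probe_0001", "met_001", prepared[1]),
               "fewer than 2")
})

test_that("interaction filter keeps interaction-free pairs", {
  res <- replicate_interaction_filter(reps = 2, n_per_study = c(800, 800, 800),
                                      seed = 17)
  expect_equal(res$power, 1)
  expect_lte(res$null_removal_rate, 0.5)
  empty <- interaction_filter(data.frame(probe_id = character(0),
                                         metabolite_id = character(0)),
                              list())
  expect_equal(nrow(empty$retained), 0)
})

test_that("gene catalogue screening filters by symbol and PM", {
  med <- data.frame(probe_id = c("p1", "p2", "p3"),
                    gene_symbol = c("FANCL", "IRF4", "OTHER"),
                    significant = c(TRUE, TRUE, TRUE),
                    pm = c(0.42, 0.1, 0.9))
  res <- screen_gene_catalogue(med, c("FANCL", "IRF4"))
  expect_equal(res$gene_symbol, "FANCL")  # IRF4 below the PM cutoff
  expect_equal(nrow(screen_gene_catalogue(med, character(0))), 0)
  expect_equal(nrow(screen_gene_catalogue(med, "ABSENT")), 0)
  expect_equal(nrow(screen_gene_catalogue(med, c("FANCL", "OTHER"),
                                          pm_cut = 1.1)), 0)
  # sorted by PM descending
  res2 <- screen_gene_catalogue(med, c("FANCL", "OTHER"))
  expect_equal(res2$gene_symbol, c("OTHER", "FANCL"))
})
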