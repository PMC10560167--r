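test_that("upper-outlier rule removes only extreme log values", {
  # 100 values at log = 0 plus one at log = 25: threshold is
  # mean + 5*SD of the log values = 0.2475 + 5 * 2.4876 = 12.69 < 25
  v <- c(rep(1, 100), exp(25))
  res <- remove_upper_outliers(v)
  expect_equal(res$n_removed, 1L)
  expect_true(is.na(res$values[101]))
  expect_equal(res$values[1:100], rep(1, 100))

  # all equal: SD = 0, nothing exceeds the mean
  res_eq <- remove_upper_outliers(rep(2.5, 20))
  expect_equal(res_eq$n_removed, 0L)

  # all zeros: too few positives, warning no-op
  expect_warning(res0 <- remove_upper_outliers(rep(0, 10)), "fewer than 3")
  expect_equal(res0$values, rep(0, 10))
  expect_equal(res0$n_removed, 0L)

  # zeros are never flagged even when the threshold is tight
  vz <- c(rep(0, 5), rep(1, 50), exp(30))
  resz <- remove_upper_outliers(vz)
  expect_equal(resz$values[1:5], rep(0, 5))
  expect_equal(resz$n_removed, 1L)
})

test_that("upper-outlier removal is rare on clean log-normal data", {
  set.seed(8)
  removed <- replicate(20, remove_upper_outliers(exp(rnorm(1000)))$n_removed)
  expect_lt(mean(removed) / 1000, 0.003)
})

test_that("inverse normal transform gives Blom scores with averaged ties", {
  # median of an odd-length vector maps to qnorm(0.5) = 0
  expect_equal(inverse_normal_transform(c(5, 1, 9))[1], 0)

  # strictly monotone: perfect rank correlation
  set.seed(1)
  x <- rexp(50)
  expect_equal(cor(inverse_normal_transform(x), rank(x), method = "spearman"), 1)

  # tied pairs share the averaged-rank score, symmetric about zero
  out <- inverse_normal_transform(c(1, 1, 2, 2))
  expect_equal(out[1], out[2])
  expect_equal(out[3], out[4])
  expect_equal(out[1], -out[3])
  expect_equal(out[4], qnorm((3.5 - 3/8) / 4.25))

  # missing entries stay missing, rest computed on the observed subset
  with_na <- inverse_normal_transform(c(3, NA, 1, 2))
  expect_true(is.na(with_na[2]))
  expect_equal(with_na[4], 0)

  expect_warning(const <- inverse_normal_transform(rep(4, 6)), "constant")
  expect_equal(const, rep(0, 6))
})

test_that("empirical-Bayes batch adjustment removes a planted mean shift", {
  set.seed(77)
  n <- 500
  mat <- matrix(rnorm(20 * 2 * n), nrow = 20)
  batch <- rep(c("a", "b"), each = n)
  delta <- 1.5
  mat[, batch == "b"] <- mat[, batch == "b"] + delta
  adj <- eb_batch_adjust(mat, batch)
  mean_diff <- rowMeans(adj[, batch == "b"]) - rowMeans(adj[, batch == "a"])
  # the systematic shift is removed; what remains per feature is (shrunken)
  # sampling noise of the batch means, bounded by a few noise SDs
  expect_lt(abs(mean(mean_diff)), 0.05 * delta)
  expect_lt(max(abs(mean_diff)), 3 * sqrt(2 / n))
})

test_that("empirical-Bayes batch adjustment equalises a planted variance ratio", {
  set.seed(78)
  n <- 500
  mat <- matrix(rnorm(20 * 2 * n), nrow = 20)
  batch <- rep(c("a", "b"), each = n)
  mat[, batch == "b"] <- mat[, batch == "b"] * 2  # variance ratio 4:1
  adj <- eb_batch_adjust(mat, batch)
  var_ratio <- apply(adj[, batch == "b"], 1, var) / apply(adj[, batch == "a"], 1, var)
  expect_true(all(abs(var_ratio - 1) < 0.1))
})

test_that("batch adjustment edge cases: single batch no-op, singleton batch errors", {
  m <- matrix(rnorm(40), nrow = 4)
  expect_equal(eb_batch_adjust(m, rep("x", 10)), m, tolerance = 1e-10)
  expect_error(eb_batch_adjust(m, c(rep("a", 9), "lonely")), "lonely")
})

test_that("log2 quantile normalisation equalises sample distributions", {
  # hand-computed two-sample case: log2 quantiles {0,1,2} and {1,2,3}
  # average to {0.5, 1.5, 2.5}
  e <- rbind(s1 = c(1, 2, 4), s2 = c(2, 4, 8))
  out <- log2_quantile_normalize(e)
  expect_equal(unname(out[1, ]), c(0.5, 1.5, 2.5))
  expect_equal(unname(out[2, ]), c(0.5, 1.5, 2.5))

  # identical distributions across samples are unchanged up to log2
  e2 <- rbind(c(2, 4, 8), c(8, 2, 4))
  out2 <- log2_quantile_normalize(e2)
  expect_equal(sort(out2[1, ]), sort(log2(e2[1, ])))
  expect_equal(unname(out2[2, ]), c(3, 1, 2))

  set.seed(2)
  e3 <- matrix(rexp(50 * 20) + 0.1, nrow = 20)
  out3 <- log2_quantile_normalize(e3)
  sorted <- apply(out3, 1, sort)
  expect_lt(max(abs(sorted - sorted[, 1])), 1e-12)

  expect_error(log2_quantile_normalize(matrix(c(1, -1, 2, 3), 2)), "non-positive")
})

test_that("probe filters drop rarely expressed and batch-associated probes", {
  set.seed(4)
  n <- 300
  expr <- matrix(rnorm(n * 4, mean = 8), nrow = n,
                 dimnames = list(NULL, paste0("p", 1:4)))
  presence <- matrix(TRUE, n, 4)
  presence[, 2] <- c(rep(TRUE, 12), rep(FALSE, n - 12))  # 4% presence
  batch <- rep(c("b1", "b2", "b3"), each = 100)
  expr[batch == "b2", 3] <- expr[batch == "b2", 3] + 5  # 5-SD batch shift
  res <- filter_probes(expr, presence, batch)
  expect_setequal(res$kept, c("p1", "p4"))
  expect_equal(res$report$reason[res$report$probe_id == "p2"], "low_expression")
  expect_equal(res$report$reason[res$report$probe_id == "p3"], "batch_associated")
})

test_that("batch-clean probes survive the Bonferroni batch test", {
  set.seed(9)
  n <- 150
  expr <- matrix(rnorm(n * 200, mean = 8), nrow = n,
                 dimnames = list(NULL, sprintf("p%03d", 1:200)))
  res <- filter_probes(expr, matrix(TRUE, n, 200), rep(c("a", "b"), each = 75))
  expect_gt(length(res$kept), 197)
})

test_that("sample distance filter removes gross outliers only", {
  # identical samples: all distances zero, nothing removed
  e <- matrix(5, nrow = 10, ncol = 4, dimnames = list(paste0("s", 1:10), NULL))
  expect_equal(filter_samples_iqr(e)$kept, paste0("s", 1:10))

  set.seed(6)
  e2 <- matrix(rnorm(100 * 30), nrow = 100,
               dimnames = list(sprintf("s%03d", 1:100), NULL))
  e2[7, ] <- e2[7, ] + 100  # displaced by 100 SD in every feature
  res <- filter_samples_iqr(e2)
  expect_equal(res$report$sample_id, "s007")

  # clean Gaussian data: removal rate below 2%
  e3 <- matrix(rnorm(500 * 50), nrow = 500,
               dimnames = list(sprintf("g%03d", 1:500), NULL))
  expect_lt(nrow(filter_samples_iqr(e3)$report) / 500, 0.02)

  expect_warning(small <- filter_samples_iqr(e2[1:5, ]), "fewer than 8")
  expect_length(small$kept, 5)
})

test_that("probe-to-gene mapping reports unmapped probes and keeps shared genes", {
  map <- data.frame(probe_id = c("a", "b", "d"),
                    gene_symbol = c("G1", "G1", "G2"))
  res <- map_probes_to_genes(c("a", "b", "c"), map)
  expect_equal(res$mapped$probe_id, c("a", "b"))
  expect_equal(res$mapped$gene_symbol, c("G1", "G1"))  # two probes, one gene
  expect_equal(res$unmapped, "c")
  expect_equal(map_probes_to_genes("x", map)$unmapped, "x")
  expect_error(map_probes_to_genes("a", rbind(map, map[1, ])), "duplicate")
})

test_that("preprocess_study runs the fixed stage order and logs it", {
  ds <- small_multistudy(seed = 17, n = 120, n_probes = 15, n_mets = 4)[[1]]
  prep <- preprocess_study(ds)
  expect_equal(prep$qc$steps,
               c("metabolite_upper_outliers",
                 "metabolite_inverse_normal_transform",
                 "metabolite_eb_batch_adjust",
                 "expression_log2_quantile_normalize",
                 "expression_eb_batch_adjust",
                 "expression_probe_filters",
                 "expression_sample_filter",
                 "expression_probe_gene_mapping"))
  expect_equal(nrow(prep$expression), length(prep$log_bmi))
  expect_lt(max(abs(colMeans(prep$expression))), 1e-8)  # standardised
  expect_lt(max(abs(colMeans(prep$metabolites, na.rm = TRUE))), 0.1)
})
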