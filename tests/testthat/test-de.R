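test_that("quantile clipping: constants unchanged, outliers pulled in, identity", {
  g <- rep(1, 10)
  m <- cbind(g, c(rep(0, 9), 1000))
  lab <- rep("x", 10)
  out <- clip_quantiles(m, lab)
  expect_equal(out[, 1], g, ignore_attr = TRUE)
  # the outlier comes down to the group's 0.98 quantile
  q98 <- unname(quantile(m[, 2], 0.98, type = 7))
  expect_equal(max(out[, 2]), q98)
  expect_lt(max(out[, 2]), 1000)
  # q = (0, 1) is the identity
  expect_equal(clip_quantiles(m, lab, 0, 1), m, ignore_attr = TRUE)
  # clipping respects group boundaries
  m2 <- matrix(c(rep(0, 5), rep(100, 5)), ncol = 1)
  out2 <- clip_quantiles(m2, rep(c("a", "b"), each = 5))
  expect_equal(out2, m2, ignore_attr = TRUE)
  expect_error(clip_quantiles(m, lab, space = "lognorm"), "raw-counts-only")
})

test_that("two-part LRT: identical groups give p ~ 1, all-zero genes give 1", {
  set.seed(1)
  v <- rpois(50, 3)
  m <- matrix(c(v, v), ncol = 1)      # same cells duplicated in both groups
  lab <- rep(c("a", "b"), each = 50)
  expect_gt(lrt_test(m, lab)[1], 0.99)
  m0 <- matrix(0, 100, 2)
  expect_equal(lrt_test(m0, lab), c(1, 1))
  expect_error(lrt_test(m, rep("a", 100)), "two groups")
})

test_that("two-part LRT is calibrated under the null", {
  set.seed(42)
  n1 <- 150; n2 <- 250; G <- 2000
  lambda <- exp(rnorm(G, 0, 1))
  m <- matrix(rpois((n1 + n2) * G, rep(lambda, each = n1 + n2)), n1 + n2, G)
  lab <- rep(c("A", "B"), c(n1, n2))
  pv <- lrt_test(m, lab)
  type1 <- mean(pv < 0.05)
  expect_gt(type1, 0.03)
  expect_lt(type1, 0.07)
  informative <- apply(m, 2, function(v) any(v > 0))
  expect_gt(stats::ks.test(pv[informative], "punif")$p.value, 0.01)
})

test_that("two-part LRT detects large shifts, in agreement with permutation", {
  set.seed(7)
  n <- 200
  lab <- rep(c("A", "B"), each = n)
  m <- matrix(rpois(2 * n * 20, rep(rep(c(8, 2), each = n), 20)), 2 * n, 20)
  pv <- lrt_test(m, lab)
  expect_true(all(pv < 1e-6))
  # permutation oracle on the difference of means for a few genes
  for (j in 1:5) {
    obs <- mean(m[lab == "A", j]) - mean(m[lab == "B", j])
    perm <- replicate(200, {
      sh <- sample(lab)
      mean(m[sh == "A", j]) - mean(m[sh == "B", j])
    })
    p_perm <- (1 + sum(abs(perm) >= abs(obs))) / 201
    expect_lt(p_perm, 0.01)   # the oracle agrees the shift is real
  }
})

test_that("log fold change: identity, hand value, antisymmetry, spaces", {
  m <- matrix(rpois(40, 5), 20, 2)
  lab <- rep(c("a", "b"), each = 10)
  same <- rbind(m[1:10, ], m[1:10, ])
  expect_equal(log_fold_change(same, lab, "raw"), c(0, 0), ignore_attr = TRUE)
  # raw means 8 vs 2 with eps -> 0: log2(4) = 2
  m2 <- matrix(c(rep(8, 10), rep(2, 10)), ncol = 1)
  expect_equal(log_fold_change(m2, lab, "raw", eps = 1e-12), 2,
               ignore_attr = TRUE, tolerance = 1e-9)
  # sign flips when groups swap
  lab_swap <- rep(c("b", "a"), each = 10)
  expect_equal(log_fold_change(m2, lab, "raw"),
               -log_fold_change(m2, lab_swap, "raw"), ignore_attr = TRUE)
  # lognorm: difference of means over ln 2
  ml <- matrix(c(rep(2, 10), rep(1, 10)), ncol = 1)
  expect_equal(log_fold_change(ml, lab, "lognorm"), 1 / log(2),
               ignore_attr = TRUE)
})

test_that("call_degs: threshold limits and hand enumeration", {
  p <- c(1e-10, 1e-8, 0.5, 1e-9, 0.04)
  lfc <- c(2, -1.5, 3, 0.1, -0.3)
  genes <- paste0("g", 1:5)
  inf_call <- call_degs(p, lfc, genes, Inf)
  expect_length(inf_call$up, 0)
  expect_length(inf_call$down, 0)
  # threshold 0: all significant genes split by sign
  z <- call_degs(p, lfc, genes, 0, alpha = 0.05)
  padj <- p.adjust(p, "BH")
  expect_setequal(z$up, genes[padj < 0.05 & lfc > 0])
  expect_setequal(z$down, genes[padj < 0.05 & lfc < 0])
  # hand check at threshold 1: g1 up (padj tiny, lfc 2), g2 down
  c1 <- call_degs(p, lfc, genes, 1)
  expect_setequal(c1$up, "g1")
  expect_setequal(c1$down, "g2")
  expect_error(call_degs(p, lfc, genes, -1), "threshold")
})

test_that("f1_deg: agreement, disjoint, hand value, empty-set conventions", {
  expect_equal(f1_deg(c("a", "b"), c("a", "b")), 1)
  expect_equal(f1_deg(c("a"), c("b")), 0)
  expect_equal(f1_deg(c("a", "b", "c"), c("b", "c", "d")), 2 / 3)
  expect_equal(f1_deg(character(0), character(0)), 1)
  expect_equal(f1_deg(character(0), "a"), 0)
  expect_equal(f1_deg("a", character(0)), 0)
})

test_that("f1_auc: constants, hand trapezoid, refinement invariance", {
  grid <- seq(0, 1, by = 0.05)
  expect_equal(f1_auc(grid, rep(1, 21)), 1)
  expect_equal(f1_auc(grid, rep(0.5, 21)), 0.5)
  # piecewise-linear toy curve on grid (0, 1, 2): trapezoids by hand
  expect_equal(f1_auc(c(0, 1, 2), c(1, 0.5, 0)), (0.75 + 0.25) / 2)
  # refining a piecewise-linear curve leaves the AUC unchanged
  t1 <- c(0, 0.5, 1); f1v <- c(0.2, 0.8, 0.4)
  t2 <- seq(0, 1, by = 0.25)
  f2v <- approx(t1, f1v, xout = t2)$y
  expect_equal(f1_auc(t1, f1v), f1_auc(t2, f2v), tolerance = 1e-6)
  expect_error(f1_auc(1, 1), "two grid points")
  expect_error(f1_auc(c(1, 0), c(0, 1)), "increasing")
})

noiseless_sim <- function(seed = 3) {
  # huge effects, no batch effect, no dropout, generous depth
  simulate_counts(sim_config(
    n_genes = 300, celltype_sizes = c(200, 200), batch_sizes = c(200, 200),
    de_prob = 0.25, de_logfc_location = log(10), de_logfc_scale = 0.1,
    batch_logfc_scale = 0, libsize_location = log(30000), libsize_scale = 0.1,
    mean_shape = 3, mean_rate = 0.3, normalize_library = FALSE, seed = seed))
}

test_that("supervised DE on a noiseless large-effect fixture recovers truth fully", {
  sim <- noiseless_sim()
  res <- de_benchmark(sim$dataset, sim$truth, mode = "supervised")
  expect_equal(res$auc_up, 1)
  expect_equal(res$auc_down, 1)
  expect_true(all(res$f1_up == 1))
  expect_true(all(res$f1_down == 1))
})

test_that("supervised DE dominates unsupervised on the same fixture", {
  sim <- simulate_counts(sim_config(
    n_genes = 400, celltype_sizes = c(150, 350), batch_sizes = c(250, 250),
    de_prob = 0.2, de_logfc_location = log(2.5), de_logfc_scale = 0.3,
    batch_logfc_scale = 0.6, seed = 11))
  sup <- de_benchmark(sim$dataset, sim$truth, mode = "supervised", seed = 2)
  uns <- de_benchmark(sim$dataset, sim$truth, mode = "unsupervised", seed = 2)
  expect_gte(sup$auc_up + 1e-9, uns$auc_up)
  expect_gte(sup$auc_down + 1e-9, uns$auc_down)
})

test_that("type-I error is controlled after multiple-testing correction", {
  # no DE, no batch effect: the fraction of genes called at alpha = 0.05
  # after BH correction stays below 0.07
  sim <- simulate_counts(sim_config(
    n_genes = 1000, celltype_sizes = c(150, 250), batch_sizes = c(200, 200),
    de_prob = 0, batch_logfc_scale = 0, seed = 13))
  res <- de_benchmark(sim$dataset, sim$truth, mode = "supervised")
  called <- mean(res$per_gene$padj < 0.05)
  expect_lte(called, 0.07)
})

test_that("de_benchmark covers raw clipping, HVG restriction and tidiers", {
  sim <- noiseless_sim(seed = 5)
  res_hvg <- de_benchmark(sim$dataset, sim$truth, mode = "supervised",
                          genes = "hvg", hvg_n = 150)
  expect_identical(nrow(res_hvg$per_gene), 150L)
  expect_true(all(res_hvg$per_gene$gene %in% sim$dataset$gene_ids))
  td <- tidy(res_hvg)
  expect_s3_class(td, "tbl_df")
  expect_setequal(unique(td$call), intersect(c("up", "down", "none"),
                                             unique(td$call)))
  g <- glance(res_hvg)
  expect_identical(g$mode, "supervised")
  expect_identical(g$genes, "hvg")
  # lognorm route
  res_ln <- de_benchmark(log_normalize(sim$dataset), sim$truth,
                         mode = "supervised")
  expect_gt(res_ln$auc_up, 0.8)
})

test_that("cluster-to-type mapping resolves by majority overlap", {
  ns <- asNamespace("scaif")
  ct <- factor(c("a", "a", "a", "b", "b"))
  cl <- c(1, 1, 1, 2, 2)
  expect_identical(as.character(ns$map_clusters_to_types(cl, ct)),
                   c("a", "a", "a", "b", "b"))
  # when per-cluster majorities collapse (here a full tie), the one-to-one
  # assignment keeps both groups; lexical order breaks the remaining tie
  ct2 <- factor(c("a", "b", "a", "b"))
  cl2 <- c(1, 1, 2, 2)
  mapped <- suppressMessages(ns$map_clusters_to_types(cl2, ct2))
  expect_identical(as.character(mapped), c("a", "a", "b", "b"))
})
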