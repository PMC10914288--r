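#' Embed cells for metric computation
#'
#' t-SNE (suited to small datasets), UMAP (larger ones), or plain PCA, with
#' an optional preliminary PCA step before t-SNE/UMAP.
#'
#' @param matrix Numeric cells x genes matrix (finite entries).
#' @param method `"tsne"`, `"umap"` or `"pca"`.
#' @param n_components Embedding dimension (default 2).
#' @param seed Integer seed; fixed seed gives a fixed embedding.
#' @param pca_first Run PCA down to `pca_dims` components before t-SNE/UMAP.
#' @param pca_dims Components kept by the preliminary PCA.
#' @param perplexity t-SNE perplexity; capped automatically for small n.
#' @return Numeric cells x n_components matrix.
#' @export
embed_cells <- function(matrix, method = c("tsne", "umap", "pca"),
                        n_components = 2, seed = 1L, pca_first = FALSE,
                        pca_dims = 50, perplexity = 30) {
  method <- match.arg(method)
  matrix <- as.matrix(matrix)
  if (!all(is.finite(matrix))) stop("embedding input must be finite")
  if (nrow(matrix) < n_components) {
    stop("fewer cells than embedding components")
  }
  X <- matrix
  if (pca_first || method == "pca") {
    dims <- min(pca_dims, nrow(X) - 1L, ncol(X))
    X <- stats::prcomp(X, rank. = if (method == "pca") n_components else dims,
                       center = TRUE, scale. = FALSE)$x
    if (method == "pca") return(unname(X[, seq_len(n_components), drop = FALSE]))
  }
  set.seed(seed)
  if (method == "tsne") {
    perp <- min(perplexity, floor((nrow(X) - 1) / 3))
    out <- Rtsne::Rtsne(X, dims = n_components, perplexity = perp,
                        check_duplicates = FALSE, pca = ncol(X) > 50,
                        verbose = FALSE)$Y
  } else {
    out <- uwot::umap(X, n_components = n_components,
                      n_neighbors = min(15, nrow(X) - 1),
                      n_threads = 1, n_sgd_threads = 1)
  }
  unname(as.matrix(out))
}

#' Cluster an embedding
#'
#' K-means (with `k` centers) or Louvain community detection on a shared
#' nearest-neighbor graph at a given resolution.
#'
#' @param embedding Numeric cells x components matrix.
#' @param method `"kmeans"` or `"louvain"`.
#' @param k Number of clusters for k-means (required there).
#' @param resolution Louvain resolution (default 1).
#' @param knn Neighborhood size of the Louvain graph.
#' @param seed Integer seed.
#' @return Integer vector of cluster labels, one per cell.
#' @export
cluster_cells <- function(embedding, method = c("kmeans", "louvain"),
                          k = NULL, resolution = 1, knn = 15, seed = 1L) {
  method <- match.arg(method)
  embedding <- as.matrix(embedding)
  if (!all(is.finite(embedding))) stop("embedding must be finite")
  set.seed(seed)
  if (method == "kmeans") {
    if (is.null(k)) stop("k is required for k-means")
    if (k > nrow(embedding)) stop("k exceeds the number of cells")
    return(stats::kmeans(embedding, centers = k, nstart = 10,
                         iter.max = 100)$cluster)
  }
  g <- knn_graph(embedding, knn)
  comm <- igraph::cluster_louvain(g, resolution = resolution)
  as.integer(igraph::membership(comm))
}

knn_graph <- function(embedding, knn) {
  n <- nrow(embedding)
  knn <- min(knn, n - 1L)
  d <- as.matrix(stats::dist(embedding))
  edges <- integer(0)
  for (i in seq_len(n)) {
    nb <- order(d[i, ])[2:(knn + 1L)]
    edges <- c(edges, rbind(i, nb))
  }
  g <- igraph::graph_from_edgelist(matrix(edges, ncol = 2, byrow = TRUE),
                                   directed = FALSE)
  igraph::simplify(g)
}

#' Evaluation protocol settings
#'
#' @param embedder `"tsne"`, `"umap"` or `"pca"`.
#' @param clusterer `"kmeans"` or `"louvain"`.
#' @param n_seeds Seeds per metric; per-metric maxima over seeds are reported.
#' @param subsample_frac Fraction of embedded cells per robustness rep.
#' @param n_reps Robustness repetitions.
#' @param lisi_perplexity LISI perplexity.
#' @param resolution Louvain resolution.
#' @param pca_first Preliminary PCA before embedding.
#' @return An `eval_protocol` list.
#' @export
eval_protocol <- function(embedder = "tsne", clusterer = "kmeans",
                          n_seeds = 20, subsample_frac = 0.8, n_reps = 20,
                          lisi_perplexity = 30, resolution = 1,
                          pca_first = FALSE) {
  if (subsample_frac <= 0 || subsample_frac > 1) {
    stop("subsample_frac must lie in (0, 1]")
  }
  if (n_seeds < 1 || n_reps < 1) stop("n_seeds and n_reps must be >= 1")
  structure(as.list(environment()), class = "eval_protocol")
}

#' Clustering-based integration metrics
#'
#' Embeds the data once per seed, clusters, and computes ARI, ASW and LISI in
#' the cell-type-purity and batch-mixing flavors; per-metric maxima over
#' seeds are reported (so single lousy clusterings do not penalize the data).
#' Scaled scores combine into a harmonic-mean F1 per metric:
#' ARI uses the cell-type ARI directly with mixing `1 - ARI_batch`; ASW uses
#' the raw silhouettes clamped to \[0,1\] with mixing `1 - ASW_batch`; LISI
#' normalizes `(LISI_batch - 1)/(K_b - 1)` and `(K_ct - LISI_ct)/(K_ct - 1)`.
#'
#' @param matrix Cells x genes (or already-corrected) matrix.
#' @param batch Batch labels per cell.
#' @param cell_type Cell-type labels per cell.
#' @param protocol An [eval_protocol()].
#' @param seed Base seed; per-repeat seeds are `seed + 0:(n_seeds-1)`.
#' @return An `integration_eval` object: tibble of per-seed scores plus
#'   per-metric maxima (`$summary`) with scaled CT/mixing scores and F1.
#' @export
evaluate_integration <- function(matrix, batch, cell_type,
                                 protocol = eval_protocol(), seed = 1L) {
  batch <- as.factor(batch); cell_type <- as.factor(cell_type)
  if (length(batch) != nrow(matrix) || length(cell_type) != nrow(matrix)) {
    stop("label lengths must match the number of cells")
  }
  if (anyNA(batch) || anyNA(cell_type)) stop("labels must be complete")
  rows <- vector("list", protocol$n_seeds)
  for (i in seq_len(protocol$n_seeds)) {
    s <- seed + i - 1L
    emb <- embed_cells(matrix, protocol$embedder, seed = s,
                       pca_first = protocol$pca_first)
    rows[[i]] <- metric_flavors(emb, batch, cell_type, protocol, s)
  }
  per_seed <- dplyr::bind_rows(rows)
  summary <- per_seed |>
    tidyr::pivot_longer(-seed, names_to = "score", values_to = "value") |>
    dplyr::group_by(.data$score) |>
    dplyr::summarise(max = max(.data$value), .groups = "drop")
  smax <- stats::setNames(summary$max, summary$score)
  K_b <- nlevels(droplevels(batch)); K_ct <- nlevels(droplevels(cell_type))
  bundles <- tibble::tibble(
    metric = c("ari", "asw", "lisi"),
    ct_score = unname(c(smax["ari_ct"], smax["asw_ct"], smax["lisi_ct"])),
    batch_score = unname(c(smax["ari_batch"], smax["asw_batch"],
                           smax["lisi_batch"])),
    ct_scaled = unname(c(clamp01(smax["ari_ct"]),
                         clamp01(smax["asw_ct"]),
                         scale_lisi_ct(smax["lisi_ct"], K_ct))),
    mixing_scaled = unname(c(clamp01(1 - smax["ari_batch"]),
                             clamp01(1 - smax["asw_batch"]),
                             scale_lisi_batch(smax["lisi_batch"], K_b)))
  )
  bundles$f1 <- mapply(f1_combine, bundles$ct_scaled, bundles$mixing_scaled)
  structure(list(per_seed = per_seed, summary = bundles,
                 n_batches = K_b, n_celltypes = K_ct),
            class = "integration_eval")
}

scale_lisi_batch <- function(x, K) if (K <= 1) 0 else clamp01((x - 1) / (K - 1))
scale_lisi_ct <- function(x, K) if (K <= 1) 1 else clamp01((K - x) / (K - 1))

metric_flavors <- function(emb, batch, cell_type, protocol, s) {
  cl_ct <- cluster_cells(emb, protocol$clusterer,
                         k = nlevels(droplevels(cell_type)),
                         resolution = protocol$resolution, seed = s)
  cl_b <- if (protocol$clusterer == "kmeans" &&
              nlevels(droplevels(batch)) != nlevels(droplevels(cell_type))) {
    cluster_cells(emb, protocol$clusterer, k = nlevels(droplevels(batch)),
                  resolution = protocol$resolution, seed = s)
  } else cl_ct
  perp <- min(protocol$lisi_perplexity, nrow(emb) - 1L)
  tibble::tibble(
    seed = s,
    ari_ct = adjusted_rand_index(cl_ct, cell_type),
    ari_batch = adjusted_rand_index(cl_b, batch),
    asw_ct = silhouette_width(emb, cell_type),
    asw_batch = silhouette_width(emb, batch),
    lisi_ct = lisi(emb, cell_type, perp)$median,
    lisi_batch = lisi(emb, batch, perp)$median
  )
}

#' @export
print.integration_eval <- function(x, ...) {
  cat("<integration_eval> per-metric maxima over",
      nrow(x$per_seed), "seeds\n")
  print(as.data.frame(x$summary), row.names = FALSE, digits = 3)
  invisible(x)
}

#' Average of min-max standardized F1 scores across methods
#'
#' The three per-metric F1 scores of each method are min-max standardized
#' across the compared methods and averaged. With fewer than two methods the
#' raw mean is returned with a warning (standardization is undefined).
#'
#' @param evals Named list of `integration_eval` objects, one per method.
#' @return Tibble with columns `method` and `avg_f1`.
#' @export
average_f1 <- function(evals) {
  f1s <- vapply(evals, function(e) e$summary$f1, numeric(3))
  rownames(f1s) <- c("ari", "asw", "lisi")
  if (length(evals) < 2) {
    warning("fewer than two methods: returning raw mean F1 without standardization")
    return(tibble::tibble(method = names(evals) %||% "method_1",
                          avg_f1 = mean(f1s)))
  }
  std <- apply(f1s, 1, function(v) {
    r <- max(v) - min(v)
    if (r == 0) rep(0.5, length(v)) else (v - min(v)) / r
  })  # methods x metrics
  tibble::tibble(method = names(evals) %||% paste0("method_", seq_along(evals)),
                 avg_f1 = unname(rowMeans(std)))
}

#' Subsample robustness protocol
#'
#' Embeds once, then repeatedly subsamples a fraction of the embedded cells,
#' recomputes clustering and all metric flavors per repetition, and returns
#' distribution summaries (mean, sd, min, max) per score.
#'
#' @inheritParams evaluate_integration
#' @return A tibble with one row per score and columns mean/sd/min/max, plus
#'   the per-rep tibble in attribute `"per_rep"`.
#' @export
robust_evaluate <- function(matrix, batch, cell_type,
                            protocol = eval_protocol(), seed = 1L) {
  batch <- as.factor(batch); cell_type <- as.factor(cell_type)
  emb <- embed_cells(matrix, protocol$embedder, seed = seed,
                     pca_first = protocol$pca_first)
  n <- nrow(emb)
  rows <- vector("list", protocol$n_reps)
  for (r in seq_len(protocol$n_reps)) {
    s <- seed + r - 1L
    set.seed(s)
    idx <- sample.int(n, max(2L, round(protocol$subsample_frac * n)))
    rows[[r]] <- metric_flavors(emb[idx, , drop = FALSE],
                                droplevels(batch[idx]),
                                droplevels(cell_type[idx]), protocol, s)
  }
  per_rep <- dplyr::bind_rows(rows)
  out <- per_rep |>
    tidyr::pivot_longer(-seed, names_to = "score", values_to = "value") |>
    dplyr::group_by(.data$score) |>
    dplyr::summarise(mean = mean(.data$value),
                     sd = ifelse(dplyr::n() > 1, stats::sd(.data$value), 0),
                     min = min(.data$value), max = max(.data$value),
                     .groups = "drop")
  attr(out, "per_rep") <- per_rep
  out
}
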