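#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions via the pair-counting
#' contingency formula.
#'
#' @param labels_a,labels_b Vectors of cluster labels (any type), equal length.
#' @return Scalar <= 1; 1 for identical partitions, ~0 at random.
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    stop("label vectors must have equal length")
  }
  tab <- table(labels_a, labels_b)
  n <- length(labels_a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  total <- choose(n, 2)
  expected <- sum_a * sum_b / total
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)   # both partitions trivial
  (sum_ij - expected) / (max_idx - expected)
}

#' Average silhouette width
#'
#' Mean silhouette over cells with Euclidean distances in the embedding:
#' cohesion (mean distance to own cluster) versus separation (mean distance
#' to the nearest other cluster).
#'
#' @param embedding Numeric matrix (cells x components).
#' @param labels Cluster labels, at least two distinct values.
#' @return Scalar in \[-1, 1\].
#' @export
silhouette_width <- function(embedding, labels) {
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) < 2) {
    stop("silhouette requires at least two clusters")
  }
  sil <- cluster::silhouette(as.integer(droplevels(labels)),
                             stats::dist(embedding))
  mean(sil[, "sil_width"])
}

#' Local inverse Simpson index
#'
#' Per cell, neighborhood weights from a Gaussian kernel calibrated to the
#' target perplexity (the bandwidth is found by bisection so the weight
#' entropy equals log(perplexity), as in stochastic neighbor embedding);
#' label probabilities are the per-label weight sums, and the LISI is the
#' inverse Simpson index `1 / sum(p_l^2)` — the effective number of labels in
#' the neighborhood.
#'
#' @param embedding Numeric matrix (cells x components).
#' @param labels Label per cell (batch for mixing, cell type for purity).
#' @param perplexity Target perplexity (default 30; must be < number of cells).
#' @return A list: `per_cell` (values in \[1, #labels\]) and `median`.
#' @export
lisi <- function(embedding, labels, perplexity = 30) {
  embedding <- as.matrix(embedding)
  labels <- as.factor(labels)
  n <- nrow(embedding)
  if (perplexity >= n) stop("perplexity must be smaller than the number of cells")
  d2 <- as.matrix(stats::dist(embedding))^2
  if (any(!is.finite(d2))) stop("degenerate distances in embedding")
  target <- log(perplexity)
  per_cell <- numeric(n)
  L <- one_hot(labels)
  for (i in seq_len(n)) {
    di <- d2[i, -i]
    w <- calibrate_kernel(di, target)
    p <- crossprod(L[-i, , drop = FALSE], w)
    per_cell[i] <- 1 / sum((p / sum(w))^2)
  }
  list(per_cell = per_cell, median = stats::median(per_cell))
}

calibrate_kernel <- function(d2, target, tol = 1e-5, max_iter = 64) {
  # bisection on the Gaussian precision so that entropy(w) = target;
  # shifting by the minimum distance leaves the normalized weights unchanged
  # and keeps the kernel finite when the bandwidth gets very small
  d2 <- d2 - min(d2)
  beta <- 1
  lo <- -Inf; hi <- Inf
  for (iter in seq_len(max_iter)) {
    w <- exp(-d2 * beta)
    sw <- sum(w)
    if (sw == 0) { H <- 0 } else {
      # entropy of the normalized weights
      H <- log(sw) + beta * sum(d2 * w) / sw
    }
    if (abs(H - target) < tol) break
    if (H > target) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
    else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
  }
  w / sum(w)
}

#' Harmonic-mean F1 combination of scaled scores
#'
#' Combines a cell-type-purity score and a batch-mixing score, both already
#' scaled to \[0, 1\], into `2ab / (a + b)` (0 when either is 0).
#'
#' @param ct_scaled Cell-type purity score in \[0, 1\].
#' @param batchmix_scaled Batch-mixing score in \[0, 1\].
#' @return Scalar in \[0, 1\].
#' @export
f1_combine <- function(ct_scaled, batchmix_scaled) {
  stopifnot(ct_scaled >= 0, ct_scaled <= 1,
            batchmix_scaled >= 0, batchmix_scaled <= 1)
  if (ct_scaled + batchmix_scaled == 0) return(0)
  2 * ct_scaled * batchmix_scaled / (ct_scaled + batchmix_scaled)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)
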