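#' Per-group quantile clipping of raw counts
#'
#' The two-part test is sensitive to outliers on raw counts, so each gene's
#' distribution is clipped per group to its empirical `q_low` and `q_high`
#' quantiles (type-7). Raw-count space only.
#'
#' @param matrix Cells x genes raw-count matrix.
#' @param group_labels Group label per cell.
#' @param q_low,q_high Quantile bounds (defaults 0.02 and 0.98).
#' @param space `"raw"` or `"lognorm"`; clipping refuses lognorm input.
#' @return Clipped matrix of identical shape.
#' @export
clip_quantiles <- function(matrix, group_labels, q_low = 0.02, q_high = 0.98,
                           space = "raw") {
  if (space != "raw") stop("quantile clipping is a raw-counts-only rule")
  matrix <- as.matrix(matrix)
  group_labels <- as.factor(group_labels)
  stopifnot(length(group_labels) == nrow(matrix))
  out <- matrix
  for (g in levels(group_labels)) {
    rows <- which(group_labels == g)
    sub <- matrix[rows, , drop = FALSE]
    lo <- col_quantile(sub, q_low)
    hi <- col_quantile(sub, q_high)
    lo_m <- base::matrix(lo, nrow(sub), ncol(sub), byrow = TRUE)
    hi_m <- base::matrix(hi, nrow(sub), ncol(sub), byrow = TRUE)
    out[rows, ] <- pmin(pmax(sub, lo_m), hi_m)
  }
  out
}

col_quantile <- function(m, q) {
  apply(m, 2, stats::quantile, probs = q, names = FALSE, type = 7)
}

#' Two-part likelihood-ratio test per gene
#'
#' Single-cell expression is bimodal: a point mass at zero (undetected) and a
#' continuous positive component. Per gene, the null fits one detection rate
#' and one positive-expression Gaussian mean to the pooled cells; the
#' alternative fits them per group (variance pooled across groups). The
#' statistic `2 (l_alt - l_null)` is referred to a chi-square with 2 degrees
#' of freedom.
#'
#' @param matrix Cells x genes matrix (clipped raw counts or lognorm values).
#' @param labels Two-group factor, both groups non-empty.
#' @return Numeric vector of per-gene p-values; all-zero genes get p = 1.
#' @export
lrt_test <- function(matrix, labels) {
  matrix <- as.matrix(matrix)
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 2) stop("lrt_test expects exactly two groups")
  g1 <- labels == levels(labels)[1]
  g2 <- !g1
  if (!any(g1) || !any(g2)) stop("both groups must be non-empty")
  vapply(seq_len(ncol(matrix)), function(j) {
    lrt_one_gene(matrix[g1, j], matrix[g2, j])
  }, numeric(1))
}

lrt_one_gene <- function(v1, v2) {
  n1 <- length(v1); n2 <- length(v2)
  pos1 <- v1[v1 > 0]; pos2 <- v2[v2 > 0]
  k1 <- length(pos1); k2 <- length(pos2)
  k <- k1 + k2; n <- n1 + n2
  if (k == 0) return(1)

  # detection (binomial) component
  ll_bin <- function(kk, nn) {
    if (kk == 0 || kk == nn) return(0)
    p <- kk / nn
    kk * log(p) + (nn - kk) * log(1 - p)
  }
  bin_alt <- ll_bin(k1, n1) + ll_bin(k2, n2)
  bin_null <- ll_bin(k, n)

  # positive (Gaussian) component, variance pooled under the alternative
  pos <- c(pos1, pos2)
  m_null <- mean(pos)
  m1 <- if (k1 > 0) mean(pos1) else 0
  m2 <- if (k2 > 0) mean(pos2) else 0
  ss_alt <- sum((pos1 - m1)^2) + sum((pos2 - m2)^2)
  s2 <- max(ss_alt / max(k, 1), 1e-8)
  gauss_alt <- -0.5 * ss_alt / s2
  gauss_null <- -0.5 * sum((pos - m_null)^2) / s2

  stat <- 2 * ((bin_alt + gauss_alt) - (bin_null + gauss_null))
  stats::pchisq(max(stat, 0), df = 2, lower.tail = FALSE)
}

#' Per-gene base-2 log fold change between two groups
#'
#' On log-normalized values, the difference of group means divided by
#' `ln 2`; on raw counts, `log2((mean1 + eps) / (mean2 + eps))`.
#'
#' @param matrix Cells x genes matrix.
#' @param labels Two-group factor; the fold change is group 1 over group 2
#'   (first factor level over second).
#' @param space `"raw"` or `"lognorm"`.
#' @param eps Pseudocount for the raw-space ratio (default 1).
#' @return Numeric per-gene logFC vector (base 2).
#' @export
log_fold_change <- function(matrix, labels, space = c("lognorm", "raw"),
                            eps = 1) {
  space <- match.arg(space)
  matrix <- as.matrix(matrix)
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 2) stop("log_fold_change expects exactly two groups")
  g1 <- labels == levels(labels)[1]
  m1 <- colMeans(matrix[g1, , drop = FALSE])
  m2 <- colMeans(matrix[!g1, , drop = FALSE])
  if (space == "lognorm") (m1 - m2) / log(2) else log2((m1 + eps) / (m2 + eps))
}

#' Call up- and down-regulated genes
#'
#' Benjamini-Hochberg correction at `alpha`, then a log-fold-change filter:
#' up-regulated genes need `logfc > threshold`, down-regulated
#' `logfc < -threshold`.
#'
#' @param pvalue Per-gene p-values.
#' @param logfc Per-gene base-2 logFC.
#' @param gene_ids Gene identifiers.
#' @param logfc_threshold Non-negative threshold.
#' @param alpha Significance level after correction (default 0.05).
#' @return List with character sets `up` and `down`.
#' @export
call_degs <- function(pvalue, logfc, gene_ids, logfc_threshold, alpha = 0.05) {
  stopifnot(logfc_threshold >= 0)
  padj <- stats::p.adjust(pvalue, method = "BH")
  sig <- padj < alpha
  list(up = gene_ids[sig & logfc > logfc_threshold],
       down = gene_ids[sig & logfc < -logfc_threshold])
}

#' F1 score between detected and true gene sets
#'
#' Harmonic mean of precision and recall. Both sets empty counts as perfect
#' agreement (F1 = 1); exactly one empty is total disagreement (F1 = 0).
#'
#' @param detected,truth Character vectors (subsets of the gene universe).
#' @return Scalar in \[0, 1\].
#' @export
f1_deg <- function(detected, truth) {
  detected <- unique(detected); truth <- unique(truth)
  if (length(detected) == 0 && length(truth) == 0) return(1)
  if (length(detected) == 0 || length(truth) == 0) return(0)
  tp <- length(intersect(detected, truth))
  if (tp == 0) return(0)
  prec <- tp / length(detected)
  rec <- tp / length(truth)
  2 * prec * rec / (prec + rec)
}

#' Area under an F1-versus-threshold curve
#'
#' Trapezoidal integral divided by the grid range, so a constant curve at 1
#' scores 1.
#'
#' @param thresholds Increasing numeric grid (length >= 2).
#' @param f1 F1 values on the grid, in \[0, 1\].
#' @return Scalar in \[0, 1\].
#' @export
f1_auc <- function(thresholds, f1) {
  if (length(thresholds) < 2) stop("AUC needs at least two grid points")
  if (is.unsorted(thresholds, strictly = TRUE)) {
    stop("threshold grid must be strictly increasing")
  }
  stopifnot(length(f1) == length(thresholds))
  widths <- diff(thresholds)
  sum(widths * (utils::head(f1, -1) + utils::tail(f1, -1)) / 2) /
    (max(thresholds) - min(thresholds))
}

#' Differential-expression benchmark against simulation ground truth
#'
#' Obtains two-group labels (true cell types, or k-means clusters mapped to
#' cell types by majority overlap), optionally clips raw counts per group,
#' runs the two-part LRT and the logFC computation, calls DEGs across a
#' threshold grid, and scores F1-versus-threshold curves and their AUC for
#' up- and down-regulated genes separately.
#'
#' @param dataset An `expr_dataset` (corrected or not) with two cell types.
#' @param truth A `ground_truth` from [simulate_counts()].
#' @param mode `"supervised"` (true cell-type labels) or `"unsupervised"`
#'   (k-means on a PCA embedding, clusters mapped to types by overlap).
#' @param genes `"all"` or `"hvg"` (top `hvg_n` by log-expression variance).
#' @param hvg_n Number of highly variable genes retained in hvg mode.
#' @param thresholds LogFC threshold grid (base 2); default 0 to 1 by 0.05.
#' @param alpha BH-adjusted significance level.
#' @param seed Seed for the unsupervised clustering.
#' @return A `de_result`: per-gene tibble (`logfc`, `pvalue`, `call`), the
#'   F1 curves, `auc_up`, `auc_down`.
#' @export
de_benchmark <- function(dataset, truth, mode = c("supervised", "unsupervised"),
                         genes = c("all", "hvg"), hvg_n = 2000,
                         thresholds = seq(0, 1, by = 0.05), alpha = 0.05,
                         seed = 1L) {
  mode <- match.arg(mode)
  genes <- match.arg(genes)
  stopifnot(inherits(dataset, "expr_dataset"))
  if (is.null(dataset$cell_type)) stop("de_benchmark needs cell-type labels")

  labels <- de_group_labels(dataset, mode, seed)
  mat <- dataset$matrix
  gene_ids <- dataset$gene_ids

  if (genes == "hvg") {
    logm <- if (dataset$space == "lognorm") mat else log1p(mat)
    keep <- order(apply(logm, 2, stats::var), decreasing = TRUE)[
      seq_len(min(hvg_n, ncol(mat)))]
    keep <- sort(keep)
    mat <- mat[, keep, drop = FALSE]
    gene_ids <- gene_ids[keep]
  }

  if (dataset$space == "raw") {
    mat <- clip_quantiles(mat, labels, space = dataset$space)
  }
  pvalue <- lrt_test(mat, labels)
  logfc <- log_fold_change(mat, labels, space = dataset$space)

  up_truth <- intersect(truth$up_genes, gene_ids)
  down_truth <- intersect(truth$down_genes, gene_ids)
  f1_up <- f1_down <- numeric(length(thresholds))
  for (i in seq_along(thresholds)) {
    called <- call_degs(pvalue, logfc, gene_ids, thresholds[i], alpha)
    tl <- abs(truth$true_logfc[gene_ids])
    f1_up[i] <- f1_deg(called$up,
                       intersect(up_truth, gene_ids[tl > thresholds[i]]))
    f1_down[i] <- f1_deg(called$down,
                         intersect(down_truth, gene_ids[tl > thresholds[i]]))
  }
  padj <- stats::p.adjust(pvalue, method = "BH")
  call <- rep("none", length(gene_ids))
  call[padj < alpha & logfc > 0] <- "up"
  call[padj < alpha & logfc < 0] <- "down"
  structure(list(
    per_gene = tibble::tibble(gene = gene_ids, logfc = logfc,
                              pvalue = pvalue, padj = padj, call = call),
    thresholds = thresholds, f1_up = f1_up, f1_down = f1_down,
    auc_up = f1_auc(thresholds, f1_up),
    auc_down = f1_auc(thresholds, f1_down),
    mode = mode, genes = genes, space = dataset$space
  ), class = "de_result")
}

de_group_labels <- function(dataset, mode, seed) {
  if (mode == "supervised") {
    labels <- droplevels(dataset$cell_type)
    if (nlevels(labels) != 2) stop("supervised DE expects two cell types")
    return(labels)
  }
  emb <- embed_cells(dataset$matrix, "pca", n_components = 10, seed = seed)
  cl <- cluster_cells(emb, "kmeans", k = 2, seed = seed)
  map_clusters_to_types(cl, droplevels(dataset$cell_type))
}

map_clusters_to_types <- function(clusters, cell_type) {
  # majority-overlap mapping; ties resolved by larger overlap then lexical
  # order. When the per-cluster majorities collapse onto one type (a cluster
  # mixing two cell types), fall back to the one-to-one assignment with the
  # largest total overlap so downstream two-group tests stay defined.
  tab <- table(clusters, cell_type)
  types <- colnames(tab)
  mapping <- character(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    best <- which(tab[i, ] == max(tab[i, ]))
    mapping[i] <- types[best[order(types[best])[1]]]
  }
  if (length(unique(mapping)) < min(nrow(tab), ncol(tab)) &&
      nrow(tab) <= ncol(tab) && nrow(tab) <= 6) {
    perms <- perm_matrix(ncol(tab), nrow(tab))
    overlap <- apply(perms, 1, function(p) {
      sum(tab[cbind(seq_len(nrow(tab)), p)])
    })
    p_best <- perms[which.max(overlap), ]
    mapping <- types[p_best]
    message("cluster-to-type majority mapping collapsed; using the best ",
            "one-to-one assignment instead")
  }
  factor(mapping[match(clusters, rownames(tab))], levels = levels(cell_type))
}

perm_matrix <- function(n, r) {
  # all r-permutations of seq_len(n), rows = arrangements
  if (r == 1) return(matrix(seq_len(n), ncol = 1))
  out <- NULL
  for (i in seq_len(n)) {
    sub <- perm_matrix(n - 1, r - 1)
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub), r - 1)))
  }
  unname(out)
}

#' @export
print.de_result <- function(x, ...) {
  cat(sprintf("<de_result> %s labels, %s genes, %s space\n",
              x$mode, x$genes, x$space))
  cat(sprintf("  AUC up: %.3f  AUC down: %.3f  (grid %.2f..%.2f)\n",
              x$auc_up, x$auc_down, min(x$thresholds), max(x$thresholds)))
  invisible(x)
}
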