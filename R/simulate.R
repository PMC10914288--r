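#' Simulation configuration
#'
#' Parameters of the gamma-Poisson count simulator. The generative model:
#' per-gene base mean `lambda_g ~ Gamma(mean_shape, mean_rate)`; with
#' probability `de_prob` a gene is differentially expressed between the two
#' consecutive cell types, with a multiplicative factor of magnitude
#' `exp(de_logfc_location + de_logfc_scale * |N(0,1)|)` applied up or down
#' with equal probability; a multiplicative per-gene, per-batch factor
#' `b_gk ~ LogNormal(batch_logfc_location, batch_logfc_scale)` (reference
#' batch fixed at 1); per-cell library size `~ LogNormal(libsize_location,
#' libsize_scale)`; counts `~ Poisson(library * normalized mean)`; dropout
#' `~ Bernoulli` with probability `1 / (1 + exp(dropout_shape * (log(mu) -
#' dropout_midpoint)))`, so lowly expressed entries drop out more often.
#'
#' @param n_genes Number of genes.
#' @param celltype_sizes Integer vector of cells per cell type.
#' @param batch_sizes Integer vector of cells per batch; must sum to
#'   `sum(celltype_sizes)`.
#' @param de_prob Probability a gene is DE between consecutive cell types.
#' @param de_logfc_location,de_logfc_scale Location/scale of the lognormal DE
#'   factor magnitude (natural-log scale).
#' @param batch_logfc_location,batch_logfc_scale Lognormal parameters of the
#'   per-gene batch factors; scale 0 disables batch effects.
#' @param libsize_location,libsize_scale Lognormal library-size parameters
#'   (location on the natural-log scale, e.g. `log(2000)` for ~2000 counts).
#' @param dropout_midpoint,dropout_shape Logistic dropout parameters on the
#'   log-mean scale; `dropout_shape = 0` with `dropout_target = NULL` and
#'   `dropout_midpoint = -Inf` disables dropout.
#' @param dropout_target Optional fraction in \[0,1\): solve for the midpoint
#'   so the expected fraction of nonzero entries zeroed equals this target.
#' @param mean_shape,mean_rate Gamma parameters of per-gene base means.
#' @param normalize_library When TRUE (default), per-cell gene means are
#'   rescaled to sum to one so the expected cell total equals the library
#'   size; cell types then compete for a fixed transcriptome share
#'   (the compositional behavior of real library-size-normalized data).
#'   When FALSE, gene means act independently and strong DE in one direction
#'   does not shift the apparent expression of unrelated genes.
#' @param seed Integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 1000,
                       celltype_sizes = c(411, 989),
                       batch_sizes = c(500, 900),
                       de_prob = 0.1,
                       de_logfc_location = log(2),
                       de_logfc_scale = 0.4,
                       batch_logfc_location = 0,
                       batch_logfc_scale = 0.3,
                       libsize_location = log(2000),
                       libsize_scale = 0.3,
                       dropout_midpoint = -Inf,
                       dropout_shape = 1,
                       dropout_target = NULL,
                       mean_shape = 0.6,
                       mean_rate = 0.3,
                       normalize_library = TRUE,
                       seed = 1L) {
  if (sum(celltype_sizes) != sum(batch_sizes)) {
    stop("celltype_sizes and batch_sizes must sum to the same total (",
         sum(celltype_sizes), " vs ", sum(batch_sizes), ")")
  }
  if (de_prob < 0 || de_prob > 1) stop("de_prob must lie in [0, 1]")
  for (nm in c("de_logfc_scale", "batch_logfc_scale", "libsize_scale")) {
    if (get(nm) < 0) stop(nm, " must be non-negative")
  }
  if (!is.null(dropout_target) &&
      (dropout_target < 0 || dropout_target >= 1)) {
    stop("dropout_target must lie in [0, 1)")
  }
  structure(as.list(environment()), class = "sim_config")
}

#' Dataset3-like and Dataset4-like presets
#'
#' Two imbalanced cell types (411/989), two imbalanced batches (500/900),
#' multiplicative per-gene batch effects, and dropout targets of 0.05
#' (small, "Dataset3-like") or 0.25 (large, "Dataset4-like").
#'
#' @param n_genes Number of genes (the source simulations do not print one).
#' @param seed Integer seed.
#' @param ... Overrides passed to [sim_config()].
#' @return A `sim_config`.
#' @export
sim_config_dataset3 <- function(n_genes = 1000, seed = 1L, ...) {
  sim_config(n_genes = n_genes, dropout_target = 0.05, seed = seed, ...)
}

#' @rdname sim_config_dataset3
#' @export
sim_config_dataset4 <- function(n_genes = 1000, seed = 1L, ...) {
  sim_config(n_genes = n_genes, dropout_target = 0.25, seed = seed, ...)
}

#' Simulate a multi-batch scRNA-seq count dataset with ground truth
#'
#' @param config A [sim_config()].
#' @return A list with elements `dataset` (raw-count [expression_dataset()]
#'   with `cell_type` labels and dropout bookkeeping in the `dropout_info`
#'   attribute) and `truth` (a `ground_truth` list: `up_genes`, `down_genes`,
#'   `true_logfc` in base 2, `batch_factor` genes x batches matrix,
#'   `de_factor`).
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  d <- config$n_genes
  n <- sum(config$celltype_sizes)
  n_types <- length(config$celltype_sizes)
  n_batches <- length(config$batch_sizes)
  gene_ids <- sprintf("gene_%04d", seq_len(d))

  # per-gene base mean (relative scale; normalized per cell below)
  lambda <- stats::rgamma(d, shape = config$mean_shape, rate = config$mean_rate)
  lambda <- pmax(lambda, 1e-6)

  # DE factors between consecutive cell types; direction +-1 equally likely
  is_de <- stats::runif(d) < config$de_prob
  magnitude <- exp(config$de_logfc_location +
                     config$de_logfc_scale * abs(stats::rnorm(d)))
  direction <- sample(c(-1, 1), d, replace = TRUE)
  de_factor <- ifelse(is_de, magnitude^direction, 1)
  true_logfc <- ifelse(is_de, direction * log2(magnitude), 0)

  # type means: cell type 1 carries the DE factor, later types are the base
  type_mean <- matrix(lambda, d, n_types)
  type_mean[, 1] <- lambda * de_factor

  # per-gene multiplicative batch factor; batch 1 is the reference
  batch_factor <- matrix(1, d, n_batches,
                         dimnames = list(gene_ids, NULL))
  if (n_batches > 1 && config$batch_logfc_scale > 0) {
    for (k in 2:n_batches) {
      batch_factor[, k] <- stats::rlnorm(d, config$batch_logfc_location,
                                         config$batch_logfc_scale)
    }
  }

  # joint assignment: independent random pairing of type and batch labels
  cell_type <- rep(paste0("type", seq_len(n_types)), config$celltype_sizes)
  batch <- sample(rep(paste0("batch", seq_len(n_batches)), config$batch_sizes))

  lib <- stats::rlnorm(n, config$libsize_location, config$libsize_scale)

  ct_idx <- match(cell_type, paste0("type", seq_len(n_types)))
  b_idx <- match(batch, paste0("batch", seq_len(n_batches)))

  mu <- matrix(0, n, d)
  for (t in seq_len(n_types)) {
    for (k in seq_len(n_batches)) {
      rows <- which(ct_idx == t & b_idx == k)
      if (!length(rows)) next
      gm <- type_mean[, t] * batch_factor[, k]
      if (config$normalize_library) {
        gm <- gm / sum(gm)                      # expected cell total = library
      } else {
        gm <- gm / config$n_genes               # library sets the mean depth
      }
      mu[rows, ] <- tcrossprod(lib[rows], gm)
    }
  }

  counts <- matrix(stats::rpois(n * d, lambda = mu), n, d)

  # logistic dropout on the log-mean scale, applied to nonzero entries
  nz <- counts > 0
  n_nonzero_pre <- sum(nz)
  n_dropped <- 0L
  midpoint <- config$dropout_midpoint
  if (!is.null(config$dropout_target) && config$dropout_target > 0) {
    lmu_nz <- log(mu[nz])
    shape <- config$dropout_shape
    target <- config$dropout_target
    f <- function(m) mean(stats::plogis(shape * (m - lmu_nz))) - target
    midpoint <- stats::uniroot(f, lower = min(lmu_nz) - 50,
                               upper = max(lmu_nz) + 50, tol = 1e-8)$root
  }
  if (is.finite(midpoint)) {
    p_drop <- stats::plogis(config$dropout_shape * (midpoint - log(mu)))
    dropped <- nz & (matrix(stats::runif(n * d), n, d) < p_drop)
    counts[dropped] <- 0
    n_dropped <- sum(dropped)
  }

  ds <- expression_dataset(counts, batch = batch, cell_type = cell_type,
                           gene_ids = gene_ids,
                           cell_ids = sprintf("cell_%05d", seq_len(n)),
                           space = "raw")
  attr(ds, "dropout_info") <- list(n_nonzero_pre = n_nonzero_pre,
                                   n_dropped = n_dropped,
                                   midpoint = midpoint)
  colnames(batch_factor) <- levels(ds$batch)
  truth <- structure(
    list(up_genes = gene_ids[true_logfc > 0],
         down_genes = gene_ids[true_logfc < 0],
         true_logfc = stats::setNames(true_logfc, gene_ids),
         batch_factor = batch_factor,
         de_factor = stats::setNames(de_factor, gene_ids)),
    class = "ground_truth")
  list(dataset = ds, truth = truth)
}

#' Realized dropout fraction
#'
#' Fraction of pre-dropout nonzero count entries that were forced to zero by
#' the dropout step of [simulate_counts()].
#'
#' @param dataset An `expr_dataset` produced by [simulate_counts()].
#' @return Scalar in \[0, 1\].
#' @export
realized_dropout <- function(dataset) {
  info <- attr(dataset, "dropout_info")
  if (is.null(info)) stop("dataset carries no dropout bookkeeping")
  if (info$n_nonzero_pre == 0) return(0)
  info$n_dropped / info$n_nonzero_pre
}

#' Downsample one cell type
#'
#' Keeps `n_keep` uniformly sampled cells of the target type and every cell of
#' all other types, preserving the original row order.
#'
#' @param dataset An `expr_dataset` with `cell_type` labels.
#' @param celltype Cell-type level to downsample.
#' @param n_keep Number of cells of that type to retain.
#' @param seed Integer seed for the uniform selection.
#' @return An `expr_dataset`.
#' @export
downsample_celltype <- function(dataset, celltype, n_keep, seed = 1L) {
  stopifnot(inherits(dataset, "expr_dataset"))
  if (is.null(dataset$cell_type)) stop("dataset has no cell_type labels")
  in_type <- which(as.character(dataset$cell_type) == celltype)
  if (!length(in_type)) stop("unknown cell type: ", celltype)
  if (n_keep > length(in_type)) {
    stop("n_keep (", n_keep, ") exceeds available cells of type ",
         celltype, " (", length(in_type), ")")
  }
  set.seed(seed)
  keep <- sort(c(setdiff(seq_len(nrow(dataset$matrix)), in_type),
                 sample(in_type, n_keep)))
  out <- subset_cells(dataset, keep)
  out$cell_type <- droplevels_keep_sorted(out$cell_type)
  out
}

droplevels_keep_sorted <- function(f) {
  factor(as.character(f), levels = sort(unique(as.character(f))))
}
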