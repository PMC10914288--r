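#' Expression dataset container
#'
#' Bundles a cells-by-genes expression matrix with a per-cell batch label,
#' optional cell-type annotation, identifiers, and a `space` flag recording
#' whether entries are raw integer counts or log-normalized values.
#'
#' @param matrix Numeric cells x genes matrix (cells as rows).
#' @param batch Character or factor vector of batch labels, one per cell.
#' @param cell_type Optional character/factor vector of cell-type labels.
#' @param gene_ids Optional gene identifiers; defaults to colnames or `gene_1..d`.
#' @param cell_ids Optional cell identifiers; defaults to rownames or `cell_1..n`.
#' @param space Either `"raw"` (non-negative integer counts) or `"lognorm"`.
#' @param strict Enforce the raw-space integrality invariant (default TRUE).
#'   Batch-corrected reconstructions live in raw space but are continuous;
#'   the readers construct them with `strict = FALSE`.
#'
#' @return An object of class `expr_dataset`: a list with elements `matrix`,
#'   `batch` (factor with levels in sorted order), `cell_type` (factor or
#'   NULL), `gene_ids`, `cell_ids`, `space`.
#' @export
expression_dataset <- function(matrix, batch, cell_type = NULL,
                               gene_ids = NULL, cell_ids = NULL,
                               space = c("raw", "lognorm"), strict = TRUE) {
  space <- match.arg(space)
  matrix <- as.matrix(matrix)
  storage.mode(matrix) <- "double"
  n <- nrow(matrix)
  d <- ncol(matrix)
  if (is.null(gene_ids)) {
    gene_ids <- colnames(matrix) %||% paste0("gene_", seq_len(d))
  }
  if (is.null(cell_ids)) {
    cell_ids <- rownames(matrix) %||% paste0("cell_", seq_len(n))
  }
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (length(gene_ids) != d) {
    stop("gene_ids has length ", length(gene_ids), " but matrix has ", d, " columns")
  }
  if (length(cell_ids) != n) {
    stop("cell_ids has length ", length(cell_ids), " but matrix has ", n, " rows")
  }
  if (length(batch) != n) {
    stop("batch has length ", length(batch), " but matrix has ", n, " rows")
  }
  # stable, sorted level order so batch indices are reproducible across runs
  batch <- factor(as.character(batch), levels = sort(unique(as.character(batch))))
  if (!is.null(cell_type)) {
    if (length(cell_type) != n) {
      stop("cell_type has length ", length(cell_type), " but matrix has ", n, " rows")
    }
    cell_type <- factor(as.character(cell_type),
                        levels = sort(unique(as.character(cell_type))))
  }
  if (space == "raw" && strict) {
    if (any(matrix < 0)) stop("raw-space matrix contains negative entries")
    if (any(abs(matrix - round(matrix)) > 1e-8)) {
      stop("raw-space matrix contains non-integer entries")
    }
  }
  dimnames(matrix) <- list(cell_ids, gene_ids)
  structure(
    list(matrix = matrix, batch = batch, cell_type = cell_type,
         gene_ids = gene_ids, cell_ids = cell_ids, space = space),
    class = "expr_dataset"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.expr_dataset <- function(x, ...) {
  cat(sprintf("<expr_dataset> %d cells x %d genes [%s]\n",
              nrow(x$matrix), ncol(x$matrix), x$space))
  cat("  batches:   ", paste(sprintf("%s (%d)", levels(x$batch), tabulate(x$batch)),
                             collapse = ", "), "\n")
  if (!is.null(x$cell_type)) {
    cat("  cell types:", paste(sprintf("%s (%d)", levels(x$cell_type),
                                       tabulate(x$cell_type)), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.expr_dataset <- function(x) dim(x$matrix)

#' Number of batches in a dataset
#' @param dataset An `expr_dataset`.
#' @return Integer count of batch levels.
#' @export
n_batches <- function(dataset) nlevels(dataset$batch)

#' Subset cells of an expression dataset
#'
#' @param dataset An `expr_dataset`.
#' @param idx Integer or logical index over cells.
#' @return An `expr_dataset` with the selected cells; factor levels are kept.
#' @export
subset_cells <- function(dataset, idx) {
  out <- dataset
  out$matrix <- dataset$matrix[idx, , drop = FALSE]
  out$batch <- dataset$batch[idx]
  out$cell_ids <- dataset$cell_ids[idx]
  if (!is.null(dataset$cell_type)) out$cell_type <- dataset$cell_type[idx]
  for (a in c("dropout_info", "scale_factors")) attr(out, a) <- NULL
  out
}

#' One-hot and fractional batch codes
#'
#' A batch code is a point on the K-simplex over the batch vocabulary: a hard
#' label is a one-hot vector, the "average batch" is the uniform vector
#' (1/K, ..., 1/K), and fractional codes are allowed as projection targets.
#' For K = 2 the scalar shorthand y in \[0,1\] maps to (1 - y, y).
#'
#' @param x A batch level name, an integer level index, a scalar in \[0,1\]
#'   (K = 2 shorthand), a length-K simplex vector, or `"average"`.
#' @param levels Character vector of batch levels (the vocabulary).
#' @return A named numeric length-K vector summing to 1.
#' @export
batch_code <- function(x, levels) {
  K <- length(levels)
  if (is.character(x) && length(x) == 1L) {
    if (identical(x, "average")) {
      code <- rep(1 / K, K)
    } else {
      i <- match(x, levels)
      if (is.na(i)) stop("unknown batch label: ", x)
      code <- numeric(K); code[i] <- 1
    }
  } else if (is.numeric(x) && length(x) == 1L) {
    if (K == 2L && x >= 0 && x <= 1 && x != floor(x)) {
      code <- c(1 - x, x)
    } else if (x == floor(x) && x >= 1 && x <= K) {
      code <- numeric(K); code[as.integer(x)] <- 1
    } else if (K == 2L && (x == 0 || x == 1)) {
      code <- c(1 - x, x)
    } else {
      stop("cannot interpret scalar ", x, " as a batch code over ", K, " batches")
    }
  } else if (is.numeric(x) && length(x) == K) {
    code <- as.numeric(x)
  } else {
    stop("cannot interpret batch code of length ", length(x), " for K = ", K)
  }
  validate_batch_code(code, K)
  names(code) <- levels
  code
}

validate_batch_code <- function(code, K) {
  if (length(code) != K) stop("batch code has length ", length(code), ", expected ", K)
  if (any(code < -1e-9) || any(code > 1 + 1e-9)) {
    stop("batch code coordinates must lie in [0, 1]")
  }
  if (abs(sum(code) - 1) > 1e-6) stop("batch code coordinates must sum to 1")
  invisible(code)
}

#' One-hot matrix for a factor of batch labels
#' @param f Factor of labels.
#' @return n x K numeric matrix with one 1 per row.
#' @keywords internal
one_hot <- function(f) {
  K <- nlevels(f)
  m <- matrix(0, length(f), K, dimnames = list(NULL, levels(f)))
  m[cbind(seq_along(f), as.integer(f))] <- 1
  m
}

#' Median-count log-normalization
#'
#' Scales every cell so that its total count equals `target_total` (by default
#' the median of per-cell totals over the dataset), then applies `log1p`
#' elementwise. The per-cell scale factors are stored in the
#' `"scale_factors"` attribute so the transform is invertible.
#'
#' @param dataset A raw-space `expr_dataset`.
#' @param target_total Optional positive scalar; defaults to the median
#'   per-cell total count.
#' @return A lognorm-space `expr_dataset`.
#' @export
log_normalize <- function(dataset, target_total = NULL) {
  stopifnot(inherits(dataset, "expr_dataset"))
  if (dataset$space != "raw") stop("log_normalize expects a raw-count dataset")
  totals <- rowSums(dataset$matrix)
  if (any(totals <= 0)) {
    stop("cells with zero total count: ",
         paste(dataset$cell_ids[totals <= 0], collapse = ", "))
  }
  if (is.null(target_total)) target_total <- stats::median(totals)
  if (target_total <= 0) stop("target_total must be positive")
  scale <- target_total / totals
  out <- dataset
  out$matrix <- log1p(dataset$matrix * scale)
  dimnames(out$matrix) <- dimnames(dataset$matrix)
  out$space <- "lognorm"
  attr(out, "scale_factors") <- scale
  attr(out, "target_total") <- target_total
  out
}
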