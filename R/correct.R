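#' Choose the reference batch
#'
#' The one-hot code of the most represented batch; ties break to the
#' lexicographically smallest batch label.
#'
#' @param dataset An `expr_dataset`.
#' @return A named one-hot batch code.
#' @export
choose_reference <- function(dataset) {
  stopifnot(inherits(dataset, "expr_dataset"))
  counts <- tabulate(dataset$batch, nlevels(dataset$batch))
  # levels are sorted, so which.max's first-hit rule is the lexical tie-break
  batch_code(levels(dataset$batch)[which.max(counts)], levels(dataset$batch))
}

#' Project all cells onto an arbitrary batch code
#'
#' Every cell is encoded, `n_samples` latent vectors are drawn by
#' reparameterization, each is decoded conditionally on `code` (the same for
#' all cells), and the reconstructions are averaged. Averaging over repeated
#' samples addresses the stochasticity of the latent draw; its variance
#' scales as 1/S.
#'
#' @param model A trained [aif_model()].
#' @param dataset An `expr_dataset` with the model's gene set; cells unseen
#'   at training are fine.
#' @param code A [batch_code()] over the model's batch vocabulary: one-hot,
#'   fractional, or the uniform "average" code.
#' @param n_samples Number of latent draws per cell (S >= 1).
#' @param seed Integer seed for the latent draws.
#' @return An `expr_dataset` with identical shape, cell order and gene ids;
#'   batch labels are preserved as metadata while expression now lives in the
#'   target batch's space.
#' @export
project_to <- function(model, dataset, code, n_samples = 10, seed = 1L) {
  stopifnot(inherits(model, "aif_model"), inherits(dataset, "expr_dataset"),
            n_samples >= 1)
  check_gene_match(model, dataset)
  K <- length(model$batch_levels)
  code <- validate_batch_code(as.numeric(code), K)
  enc <- aif_encode(model, dataset$matrix)
  set.seed(seed)
  acc <- matrix(0, nrow(dataset$matrix), model$n_genes)
  for (s in seq_len(n_samples)) {
    z <- sample_latent(enc$mu, enc$sigma2)$z
    acc <- acc + aif_decode(model, z, code)
  }
  out <- dataset
  out$matrix <- acc / n_samples
  dimnames(out$matrix) <- list(dataset$cell_ids, dataset$gene_ids)
  out$space <- model$space
  attr(out, "projection_code") <- code
  out
}

#' Batch-effect correction onto the reference batch
#'
#' Projects every cell onto the reference batch (by default the most
#' represented one) via [project_to()].
#'
#' @inheritParams project_to
#' @param reference `"most_represented"` or anything [batch_code()] accepts
#'   (a batch label, `"average"`, a scalar for two batches, or a simplex
#'   vector).
#' @return A corrected `expr_dataset`; see [project_to()].
#' @export
correct_batches <- function(model, dataset, reference = "most_represented",
                            n_samples = 10, seed = 1L) {
  code <- if (identical(reference, "most_represented")) {
    choose_reference(dataset)
  } else {
    batch_code(reference, model$batch_levels)
  }
  project_to(model, dataset, code, n_samples = n_samples, seed = seed)
}

check_gene_match <- function(model, dataset) {
  if (ncol(dataset$matrix) != model$n_genes) {
    stop("gene-set mismatch: model expects ", model$n_genes, " genes, dataset has ",
         ncol(dataset$matrix))
  }
  genes_model <- attr(model, "gene_ids")
  if (!is.null(genes_model)) {
    missing <- setdiff(genes_model, dataset$gene_ids)
    extra <- setdiff(dataset$gene_ids, genes_model)
    if (length(missing) || length(extra)) {
      stop("gene-set mismatch; missing: ",
           paste(utils::head(missing, 5), collapse = ", "),
           "; extra: ", paste(utils::head(extra, 5), collapse = ", "))
    }
  }
  invisible(TRUE)
}
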