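#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a training loss report
#'
#' @param x An `aif_loss_report`.
#' @param ... Unused.
#' @return A long tibble: `epoch`, `loss` (term name), `value` (raw),
#'   `normalizer`, `normalized` (value / normalizer).
#' @export
tidy.aif_loss_report <- function(x, ...) {
  e <- x$epochs_completed
  if (e == 0) {
    return(tibble::tibble(epoch = integer(), loss = character(),
                          value = numeric(), normalizer = numeric(),
                          normalized = numeric()))
  }
  raw <- tibble::as_tibble(as.data.frame(x$losses[seq_len(e), , drop = FALSE]))
  raw$epoch <- seq_len(e)
  nrm <- tibble::as_tibble(as.data.frame(x$normalizers[seq_len(e), , drop = FALSE]))
  nrm$epoch <- seq_len(e)
  long <- tidyr::pivot_longer(raw, -"epoch", names_to = "loss",
                              values_to = "value")
  long_n <- tidyr::pivot_longer(nrm, -"epoch", names_to = "loss",
                                values_to = "normalizer")
  out <- dplyr::left_join(long, long_n, by = c("epoch", "loss"))
  out$normalized <- out$value / out$normalizer
  out
}

#' @rdname tidy.aif_loss_report
#' @return For `glance`: a one-row tibble with epochs completed, final
#'   encoder/decoder objectives and final reconstruction loss.
#' @export
glance.aif_loss_report <- function(x, ...) {
  e <- x$epochs_completed
  tibble::tibble(
    epochs = e,
    final_rec = if (e) x$losses[e, "rec"] else NA_real_,
    final_enc_objective = if (e) x$enc_objective[e] else NA_real_,
    final_dec_objective = if (e) x$dec_objective[e] else NA_real_
  )
}

#' @export
autoplot.aif_loss_report <- function(object, normalized = FALSE, ...) {
  df <- tidy(object)
  df$y <- if (normalized) df$normalized else df$value
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$y)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~loss, scales = "free_y") +
    ggplot2::labs(x = "epoch",
                  y = if (normalized) "normalized loss" else "loss") +
    ggplot2::theme_minimal()
}

#' Tidy a differential-expression result
#'
#' @param x A `de_result`.
#' @param ... Unused.
#' @return The per-gene tibble (`gene`, `logfc`, `pvalue`, `padj`, `call`).
#' @export
tidy.de_result <- function(x, ...) x$per_gene

#' @rdname tidy.de_result
#' @return For `glance`: one row with `auc_up`, `auc_down`, mode, gene set
#'   and space.
#' @export
glance.de_result <- function(x, ...) {
  tibble::tibble(auc_up = x$auc_up, auc_down = x$auc_down, mode = x$mode,
                 genes = x$genes, space = x$space)
}

#' @export
autoplot.de_result <- function(object, ...) {
  df <- tibble::tibble(
    threshold = rep(object$thresholds, 2),
    f1 = c(object$f1_up, object$f1_down),
    direction = rep(c("up", "down"), each = length(object$thresholds))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$threshold, y = .data$f1,
                                   colour = .data$direction)) +
    ggplot2::geom_line() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "log2 fold-change threshold", y = "F1",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Tidy an integration evaluation
#'
#' @param x An `integration_eval`.
#' @param ... Unused.
#' @return The per-metric summary tibble (maxima over seeds, scaled scores,
#'   F1).
#' @export
tidy.integration_eval <- function(x, ...) x$summary

#' @rdname tidy.integration_eval
#' @export
glance.integration_eval <- function(x, ...) {
  tibble::tibble(f1_ari = x$summary$f1[x$summary$metric == "ari"],
                 f1_asw = x$summary$f1[x$summary$metric == "asw"],
                 f1_lisi = x$summary$f1[x$summary$metric == "lisi"],
                 n_seeds = nrow(x$per_seed))
}

#' @export
autoplot.integration_eval <- function(object, ...) {
  df <- tidyr::pivot_longer(object$summary,
                            c("ct_scaled", "mixing_scaled", "f1"),
                            names_to = "score", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$value,
                                   fill = .data$score)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "score", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Embedding scatter plot colored by a label
#'
#' @param embedding Cells x 2 matrix from [embed_cells()].
#' @param labels Label per cell (batch or cell type).
#' @param title Optional plot title.
#' @return A ggplot object.
#' @export
plot_embedding <- function(embedding, labels, title = NULL) {
  df <- tibble::tibble(dim1 = embedding[, 1], dim2 = embedding[, 2],
                       label = as.factor(labels))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dim1, y = .data$dim2,
                                   colour = .data$label)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.8) +
    ggplot2::labs(title = title, x = "dim 1", y = "dim 2", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
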