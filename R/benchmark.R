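#' Strong-batch-effect benchmark fixture
#'
#' Simulation preset for the package's reference benchmark: 1,500 cells
#' (batches of 600/900), two imbalanced cell types (450/1,050), 500 genes,
#' clearly separated cell types (30% DE genes at ~4-fold) under a strong
#' multiplicative batch effect (lognormal sd 0.8) — strong in the operative
#' sense that a classifier on the raw data recovers the batch almost
#' perfectly.
#'
#' @param n_genes Number of genes (default 500).
#' @param seed Integer seed.
#' @param ... Overrides passed to [sim_config()].
#' @return A `sim_config`.
#' @export
sim_config_strong_batch <- function(n_genes = 500, seed = 1L, ...) {
  sim_config(n_genes = n_genes,
             celltype_sizes = c(450, 1050), batch_sizes = c(600, 900),
             de_prob = 0.3, de_logfc_location = log(4), de_logfc_scale = 0.3,
             batch_logfc_scale = 0.8, seed = seed, ...)
}

#' Reference training recipe for the benchmark fixture
#'
#' The hyperparameters the package uses on the strong-batch fixture: a
#' 4-dimensional latent space behind 64/64 hidden layers, a linear auxiliary
#' batch classifier (a converged linear adversary removes exactly the
#' linearly decodable batch signal that post-hoc probes measure), adversaries
#' delayed for 50 epochs so the autoencoder settles first, dynamic loss
#' normalization, and loss weights dominated by reconstruction.
#'
#' @param seed Integer seed.
#' @param epochs Training epochs (default 225).
#' @return A [train_config()].
#' @export
train_config_strong_batch <- function(seed = 1L, epochs = 225) {
  train_config(
    epochs = epochs, minibatch_size = 128,
    lr_encoder = 3e-4, lr_decoder = 3e-4, lr_disc = 3e-4, lr_aux = 5e-3,
    weights = loss_weights(alpha = 0.1, rho = 0.5, beta = 0.01,
                           mu = 0.02, delta = 0.01, gamma = 0.3),
    adversarial_delay_epochs = 50, kl_free_nats = 0.25, ema_decay = 0.97,
    seed = seed
  )
}

#' Run the strong-batch benchmark end to end
#'
#' Simulates the fixture, log-normalizes, trains the adversarial model with
#' the reference recipe, and corrects onto the most represented batch.
#'
#' @param seed Integer seed driving the simulation (`seed`), model
#'   initialization (`seed + 1`), training (`seed + 2`) and correction
#'   (`seed + 3`).
#' @param epochs Training epochs.
#' @param n_samples Latent samples averaged per cell during correction.
#' @param n_genes Number of genes.
#' @return A list: `dataset` (log-normalized input), `truth`, `fit`
#'   (`model` + `report`), `corrected`.
#' @export
run_strong_batch_benchmark <- function(seed = 1L, epochs = 225,
                                       n_samples = 10, n_genes = 500) {
  sim <- simulate_counts(sim_config_strong_batch(n_genes = n_genes, seed = seed))
  ds <- log_normalize(sim$dataset)
  model <- aif_model(n_genes, levels(ds$batch), latent_dim = 4,
                     hidden = c(64, 64), disc_hidden = c(32),
                     aux_hidden = integer(0), space = "lognorm",
                     seed = seed + 1L)
  fit <- train_aif(ds, model, train_config_strong_batch(seed = seed + 2L,
                                                        epochs = epochs),
                   dyn = TRUE)
  corrected <- correct_batches(fit$model, ds, n_samples = n_samples,
                               seed = seed + 3L)
  list(dataset = ds, truth = sim$truth, fit = fit, corrected = corrected)
}

#' Cross-validated accuracy of a post-hoc batch probe
#'
#' Logistic regression (on up to 20 principal components) predicting a label
#' from a representation, scored by k-fold cross-validation. Used to quantify
#' how much batch information survives in the latent means versus the raw
#' expression matrix.
#'
#' @param X Numeric matrix (cells x features), e.g. latent means or raw data.
#' @param labels Two-level factor to predict.
#' @param folds Number of CV folds (default 5).
#' @param seed Seed for the fold assignment.
#' @return Scalar accuracy in \[0, 1\].
#' @export
probe_accuracy <- function(X, labels, folds = 5, seed = 1L) {
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 2) stop("probe_accuracy expects a two-level label")
  X <- as.matrix(X)
  pcs <- stats::prcomp(X, rank. = min(20, ncol(X), nrow(X) - 1))$x
  y <- as.integer(labels) - 1L
  set.seed(seed)
  fold <- sample(rep_len(seq_len(folds), nrow(X)))
  correct <- logical(nrow(X))
  for (f in seq_len(folds)) {
    te <- fold == f
    df <- data.frame(y = y, pcs)
    fitg <- suppressWarnings(stats::glm(y ~ ., data = df[!te, , drop = FALSE],
                                        family = stats::binomial))
    pred <- stats::predict(fitg, df[te, , drop = FALSE],
                           type = "response") > 0.5
    correct[te] <- pred == (y[te] == 1L)
  }
  mean(correct)
}

#' Majority-class rate of a label vector
#'
#' @param labels Factor or vector of labels.
#' @return The frequency of the most common label.
#' @export
majority_rate <- function(labels) {
  max(table(labels)) / length(labels)
}
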