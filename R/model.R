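#' Construct an adversarial information factorization model
#'
#' Four networks over a cells x genes expression space:
#' \describe{
#'   \item{encoder}{maps a cell `x` to diagonal-Gaussian posterior parameters
#'     `(mu, Sigma)` in a `latent_dim`-dimensional latent space plus predicted
#'     batch probabilities `y_hat` (a K-way softmax head);}
#'   \item{decoder}{maps `(z, batch code)` back to expression space;}
#'   \item{discriminator}{predicts whether a cell is original or
#'     reconstructed (the GAN adversary);}
#'   \item{auxiliary}{predicts the batch from the latent vector — trained
#'     adversarially against the encoder so the latent space ends up deprived
#'     of batch information.}
#' }
#' Backbones are fully connected stacks with leaky-rectifier activations;
#' variances are parameterized as log-variances so they stay positive.
#'
#' @param n_genes Gene dimension d.
#' @param batch_levels Character vector: the batch vocabulary (in stable,
#'   sorted order).
#' @param latent_dim Latent dimension k (default 100).
#' @param hidden Hidden widths of encoder/decoder (default `c(800, 800)`).
#' @param disc_hidden Hidden widths of the discriminator.
#' @param aux_hidden Hidden widths of the auxiliary classifier.
#' @param space Space the model is trained in (`"raw"` or `"lognorm"`),
#'   stored as preprocessing metadata.
#' @param seed Integer seed for weight initialization.
#' @return An `aif_model` object.
#' @export
aif_model <- function(n_genes, batch_levels, latent_dim = 100,
                      hidden = c(800, 800), disc_hidden = c(128),
                      aux_hidden = c(64), space = "lognorm", seed = 1L) {
  hidden <- as.integer(unlist(hidden))
  disc_hidden <- as.integer(unlist(disc_hidden))
  aux_hidden <- as.integer(unlist(aux_hidden))
  latent_dim <- as.integer(latent_dim)
  stopifnot(n_genes >= 1, latent_dim >= 1, length(batch_levels) >= 1)
  set.seed(seed)
  K <- length(batch_levels)
  h_last <- hidden[length(hidden)]
  model <- structure(list(
    trunk = mlp_init(c(n_genes, hidden), final_linear = FALSE),
    head_mu = mlp_init(c(h_last, latent_dim)),
    head_logvar = mlp_init(c(h_last, latent_dim)),
    head_cls = mlp_init(c(h_last, K)),
    decoder = mlp_init(c(latent_dim + K, rev(hidden), n_genes)),
    disc = mlp_init(c(n_genes, disc_hidden, 1)),
    aux = mlp_init(c(latent_dim, aux_hidden, K)),
    n_genes = n_genes, latent_dim = latent_dim,
    batch_levels = as.character(batch_levels), space = space,
    hidden = hidden
  ), class = "aif_model")
  model
}

#' @export
print.aif_model <- function(x, ...) {
  cat(sprintf(paste0("<aif_model> %d genes -> latent %d, %d batches (%s)\n",
                     "  encoder/decoder hidden: %s; space: %s\n"),
              x$n_genes, x$latent_dim, length(x$batch_levels),
              paste(x$batch_levels, collapse = ", "),
              paste(x$hidden, collapse = "/"), x$space))
  invisible(x)
}

#' Encode cells into the latent posterior
#'
#' @param model An `aif_model`.
#' @param x Numeric matrix (cells x genes) or a single cell vector.
#' @return A list: `mu`, `sigma2` (posterior variances, strictly positive),
#'   `logvar`, and `y_hat` (predicted batch probabilities, rows on the
#'   simplex).
#' @export
aif_encode <- function(model, x) {
  x <- as_cell_matrix(x, model$n_genes)
  fw <- encoder_forward(model, x)
  list(mu = fw$mu, sigma2 = exp(fw$logvar), logvar = fw$logvar,
       y_hat = fw$y_hat)
}

encoder_forward <- function(model, x) {
  tr <- mlp_forward(model$trunk, x)
  mu <- mlp_forward(model$head_mu, tr$out)
  lv <- mlp_forward(model$head_logvar, tr$out)
  cl <- mlp_forward(model$head_cls, tr$out)
  list(trunk = tr, mu_cache = mu, lv_cache = lv, cls_cache = cl,
       mu = mu$out, logvar = pmin(pmax(lv$out, -15), 15),
       logits = cl$out, y_hat = softmax_rows(cl$out))
}

encoder_backward <- function(model, fw, d_mu, d_logvar, d_logits) {
  # collapse the three heads into the shared trunk; returns grads per block
  b_mu <- mlp_backward(model$head_mu, fw$mu_cache, d_mu)
  b_lv <- mlp_backward(model$head_logvar, fw$lv_cache, d_logvar)
  b_cl <- mlp_backward(model$head_cls, fw$cls_cache, d_logits)
  d_trunk_out <- b_mu$d_input + b_lv$d_input + b_cl$d_input
  b_tr <- mlp_backward(model$trunk, fw$trunk, d_trunk_out)
  list(trunk = b_tr$grads, head_mu = b_mu$grads, head_logvar = b_lv$grads,
       head_cls = b_cl$grads, d_x = b_tr$d_input)
}

#' Reparameterized latent sample
#'
#' `z = mu + sqrt(sigma2) * eps` with `eps ~ N(0, I)`.
#'
#' @param mu Matrix (cells x k) of posterior means.
#' @param sigma2 Matrix of posterior variances (strictly positive).
#' @param seed Optional integer seed; when NULL the current RNG stream is used.
#' @return A list `z` (the sample) and `eps` (the standard-normal draw).
#' @export
sample_latent <- function(mu, sigma2, seed = NULL) {
  mu <- as.matrix(mu); sigma2 <- as.matrix(sigma2)
  if (any(sigma2 < 0)) stop("posterior variances must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  eps <- matrix(stats::rnorm(length(mu)), nrow(mu), ncol(mu))
  list(z = mu + sqrt(sigma2) * eps, eps = eps)
}

#' Decode latent vectors conditionally on a batch code
#'
#' @param model An `aif_model`.
#' @param z Matrix (cells x k) of latent vectors.
#' @param code Either a single batch code (recycled for every cell) or a
#'   cells x K matrix of codes; see [batch_code()].
#' @return Reconstructed expression matrix (cells x genes).
#' @export
aif_decode <- function(model, z, code) {
  z <- as.matrix(z)
  K <- length(model$batch_levels)
  if (is.null(dim(code))) {
    code <- validate_batch_code(as.numeric(code), K)
    code <- matrix(code, nrow(z), K, byrow = TRUE)
  } else {
    code <- as.matrix(code)
    apply(code, 1, validate_batch_code, K = K)
  }
  mlp_forward(model$decoder, cbind(z, code))$out
}

# ---- loss terms -----------------------------------------------------------

#' Reconstruction loss
#'
#' Sum over genes of squared differences, averaged over the minibatch.
#'
#' @param x,x_hat Matrices (cells x genes) of original and reconstructed
#'   expression.
#' @return Non-negative scalar.
#' @export
loss_reconstruction <- function(x, x_hat) {
  x <- as.matrix(x); x_hat <- as.matrix(x_hat)
  stopifnot(all(dim(x) == dim(x_hat)))
  mean(rowSums((x - x_hat)^2))
}

#' Kullback-Leibler loss to the standard-normal prior
#'
#' Closed form for a diagonal-Gaussian posterior:
#' `0.5 * (-log|Sigma| - k + mu' mu + tr(Sigma))`, averaged over the
#' minibatch.
#'
#' @param mu Matrix (cells x k) of posterior means.
#' @param sigma2 Matrix of posterior variances.
#' @return Non-negative scalar.
#' @export
loss_kl <- function(mu, sigma2) {
  mu <- as.matrix(mu); sigma2 <- as.matrix(sigma2)
  if (any(sigma2 <= 0)) stop("posterior variances must be strictly positive")
  mean(0.5 * rowSums(-log(sigma2) - 1 + mu^2 + sigma2))
}

#' Cross-entropy between predicted and target batch codes
#'
#' Standard negative cross-entropy (minimized), optionally class-weighted to
#' tackle imbalanced batches; predictions are clamped at a numerical floor so
#' the loss stays finite at saturated predictions.
#'
#' @param pred Matrix (cells x K) of predicted probabilities (or a vector for
#'   a single cell).
#' @param target Matrix/vector of target codes (one-hot or fractional).
#' @param class_weights Optional positive per-class weights; cells are
#'   weighted by their target-majority class.
#' @return Non-negative scalar.
#' @export
loss_cross_entropy <- function(pred, target, class_weights = NULL) {
  pred <- rbind_vec(pred); target <- rbind_vec(target)
  stopifnot(all(dim(pred) == dim(target)))
  p <- clamp_prob(pred)
  ce <- -rowSums(target * log(p))
  if (!is.null(class_weights)) {
    cls <- max.col(target, ties.method = "first")
    ce <- ce * class_weights[cls]
  }
  mean(ce)
}

rbind_vec <- function(x) if (is.null(dim(x))) matrix(x, nrow = 1) else as.matrix(x)

#' Inverse-frequency class weights, normalized to mean one
#'
#' @param batch Factor of batch labels.
#' @return Positive numeric vector, one weight per batch level.
#' @export
batch_class_weights <- function(batch) {
  freq <- tabulate(batch, nbins = nlevels(batch)) / length(batch)
  w <- 1 / pmax(freq, 1e-12)
  w / mean(w)
}

row_cosine <- function(a, b) {
  # cosine similarity per row; zero-norm rows contribute 0
  na <- sqrt(rowSums(a^2)); nb <- sqrt(rowSums(b^2))
  s <- rowSums(a * b)
  ok <- na > 0 & nb > 0
  out <- numeric(nrow(a))
  out[ok] <- s[ok] / (na[ok] * nb[ok])
  out
}

#' Projection constraint
#'
#' Cosine similarity between reconstructions and their projections onto the
#' average batch and onto a randomly chosen batch, summed and averaged over
#' the minibatch. Enters both training objectives with a minus sign (it is
#' maximized), encouraging reconstructions under different batch codes to
#' agree.
#'
#' @param x_hat Reconstructions (cells x genes).
#' @param x_hat_avg Decodes of the same latents under the uniform code.
#' @param x_hat_rand Decodes under per-cell random one-hot codes.
#' @return Scalar in \[-2, 2\].
#' @export
loss_projection <- function(x_hat, x_hat_avg, x_hat_rand) {
  mean(row_cosine(x_hat, x_hat_avg) + row_cosine(x_hat, x_hat_rand))
}

#' Decode latents under the average and a random batch code
#'
#' Convenience wrapper computing the two projections entering
#' [loss_projection()]: `x_hat_avg` under the uniform "average batch" code and
#' `x_hat_rand` under one-hot codes drawn uniformly from the observed batches,
#' per cell.
#'
#' @param model An `aif_model`.
#' @param z Latent matrix (cells x k).
#' @param seed Optional seed for the random batch draw.
#' @return List with `x_hat_avg`, `x_hat_rand`, `rand_code`.
#' @export
project_latents <- function(model, z, seed = NULL) {
  K <- length(model$batch_levels)
  if (!is.null(seed)) set.seed(seed)
  rand_idx <- sample.int(K, nrow(as.matrix(z)), replace = TRUE)
  rand_code <- matrix(0, nrow(as.matrix(z)), K)
  rand_code[cbind(seq_along(rand_idx), rand_idx)] <- 1
  list(x_hat_avg = aif_decode(model, z, rep(1 / K, K)),
       x_hat_rand = aif_decode(model, z, rand_code),
       rand_code = rand_code)
}

disc_prob <- function(model, x) {
  stats::plogis(mlp_forward(model$disc, x)$out[, 1])
}

#' GAN loss of the discriminator, three equally weighted cross-entropies
#'
#' `(CE(real | C(x)) + CE(fake | C(x_hat)) + CE(fake | C(x_prior))) / 3`,
#' where `x_hat` is the reconstruction of `x` and `x_prior` decodes latents
#' drawn from the prior. The same quantity enters the encoder and decoder
#' objectives with a minus sign (the adversarial term), computed on the same
#' forward pass.
#'
#' @param p_real,p_recon,p_prior Discriminator probabilities ("is original")
#'   on original cells, reconstructions, and prior decodes.
#' @return A list `disc_loss` and `adv_term` (identical by construction).
#' @export
loss_gan <- function(p_real, p_recon, p_prior) {
  l <- (binary_ce(p_real, 1) + binary_ce(p_recon, 0) + binary_ce(p_prior, 0)) / 3
  list(disc_loss = l, adv_term = l)
}

binary_ce <- function(p, target) {
  p <- clamp_prob(p)
  if (target == 1) mean(-log(p)) else mean(-log(1 - p))
}

#' Re-encoded classification loss
#'
#' Passes reconstructions back through the encoder and scores the predicted
#' batch label against the true one; reinforces that reconstructions retain
#' the batch information they were conditioned on. Gradients flow to the
#' decoder through the reconstruction.
#'
#' @param model An `aif_model`.
#' @param x_hat Reconstructions (cells x genes).
#' @param y_code Target batch codes (cells x K one-hot matrix or factor).
#' @param class_weights Optional per-class weights.
#' @return Non-negative scalar.
#' @export
reencode_class_loss <- function(model, x_hat, y_code, class_weights = NULL) {
  if (is.factor(y_code)) y_code <- one_hot(y_code)
  enc <- aif_encode(model, x_hat)
  loss_cross_entropy(enc$y_hat, y_code, class_weights)
}

as_cell_matrix <- function(x, d) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  if (ncol(x) != d) stop("expected ", d, " genes, got ", ncol(x))
  x
}

#' Loss weights of the two training objectives
#'
#' @param alpha KL weight.
#' @param rho Batch-classification weight.
#' @param beta Re-encoded classification weight.
#' @param mu Projection-constraint weight (enters with a minus sign).
#' @param delta GAN adversarial weight (minus sign).
#' @param gamma Auxiliary adversarial weight (minus sign).
#' @return A named list of non-negative weights.
#' @export
loss_weights <- function(alpha = 1, rho = 1, beta = 1, mu = 1, delta = 1,
                         gamma = 1) {
  w <- list(alpha = alpha, rho = rho, beta = beta, mu = mu, delta = delta,
            gamma = gamma)
  if (any(unlist(w) < 0)) stop("loss weights must be non-negative")
  w
}
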