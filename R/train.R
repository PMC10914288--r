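#' Training configuration
#'
#' @param epochs Number of passes over the data.
#' @param minibatch_size Cells per minibatch (must not exceed the dataset).
#' @param lr_encoder,lr_decoder,lr_disc,lr_aux Adam learning rates per network.
#' @param weights A [loss_weights()] list.
#' @param dyn_window_frac Fraction of the total epochs over which trailing
#'   medians are taken for the dynamic loss normalization (default 0.10, the
#'   "last 10 percent of the total number of epochs").
#' @param adversarial_delay_epochs Epochs during which the discriminator and
#'   auxiliary networks stay inactive (no updates, adversarial terms off).
#' @param kl_free_nats Per-dimension KL floor (free bits): latent dimensions
#'   whose KL is below this value are exempt from the prior pull, preventing
#'   posterior collapse.
#' @param ema_decay Optional per-epoch decay for Polyak averaging of the
#'   encoder and decoder weights (e.g. 0.97 averages roughly the last thirty
#'   epochs). Adversarial training oscillates around its equilibrium; the
#'   averaged generator sits near the center of the oscillation. NULL
#'   disables averaging.
#' @param class_weights `"none"` or `"inverse_frequency"` (weighted
#'   cross-entropy for imbalanced batches).
#' @param seed Integer seed governing shuffling and every latent/code draw.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 100, minibatch_size = 128,
                         lr_encoder = 1e-4, lr_decoder = 1e-4,
                         lr_disc = 1e-4, lr_aux = 1e-4,
                         weights = loss_weights(),
                         dyn_window_frac = 0.10,
                         adversarial_delay_epochs = 0,
                         kl_free_nats = 0.25,
                         ema_decay = NULL,
                         class_weights = c("none", "inverse_frequency"),
                         seed = 1L) {
  class_weights <- match.arg(class_weights)
  if (dyn_window_frac <= 0 || dyn_window_frac > 1) {
    stop("dyn_window_frac must lie in (0, 1]")
  }
  if (epochs < 0 || minibatch_size < 1) stop("invalid epochs/minibatch_size")
  structure(as.list(environment()), class = "train_config")
}

LOSS_NAMES <- c("rec", "kl", "class", "class_hat", "aux", "proj", "gan")

#' Encoder training objective
#'
#' `L_rec + alpha L_KL + rho L_class + beta L_class_hat - mu L_proj -
#'  delta L_gan - gamma L_aux`.
#'
#' @param losses Named list/vector with elements `rec`, `kl`, `class`,
#'   `class_hat`, `aux`, `proj`, `gan` (raw or normalized).
#' @param weights A [loss_weights()] list.
#' @return Scalar objective value.
#' @export
encoder_objective <- function(losses, weights) {
  losses$rec + weights$alpha * losses$kl + weights$rho * losses$class +
    weights$beta * losses$class_hat - weights$mu * losses$proj -
    weights$delta * losses$gan - weights$gamma * losses$aux
}

#' Decoder training objective
#'
#' `L_rec + beta L_class_hat - delta L_gan - mu L_proj`; independent of the
#' KL, classification and auxiliary weights.
#'
#' @inheritParams encoder_objective
#' @return Scalar objective value.
#' @export
decoder_objective <- function(losses, weights) {
  losses$rec + weights$beta * losses$class_hat -
    weights$delta * losses$gan - weights$mu * losses$proj
}

#' Dynamic loss normalizers
#'
#' For every loss term, the median of its per-epoch values over the trailing
#' window of `ceiling(window_frac * total_epochs)` epochs (truncated to the
#' available history). Dividing a raw loss by its normalizer makes the
#' normalized loss's window-median equal one. Normalizers are kept strictly
#' positive (absolute value, floored at 1e-8).
#'
#' @param report An `aif_loss_report` or a numeric matrix of per-epoch raw
#'   losses (epochs x terms).
#' @param epoch Epoch at which the window ends.
#' @param total_epochs Total planned epochs.
#' @param window_frac Window fraction (default 0.10).
#' @return Named positive numeric vector, one normalizer per loss term.
#' @export
dynamic_normalizers <- function(report, epoch, total_epochs,
                                window_frac = 0.10) {
  hist <- if (inherits(report, "aif_loss_report")) report$losses else as.matrix(report)
  if (epoch < 1 || epoch > nrow(hist)) stop("epoch outside recorded history")
  w <- min(ceiling(window_frac * total_epochs), epoch)
  window <- hist[seq(epoch - w + 1L, epoch), , drop = FALSE]
  med <- apply(window, 2, stats::median)
  pmax(abs(med), 1e-8)
}

# ---- internal: one generator forward pass under fixed random draws --------

gen_forward <- function(model, xb, Y, draws) {
  fwE <- encoder_forward(model, xb)
  sd_ <- exp(0.5 * fwE$logvar)
  z <- fwE$mu + sd_ * draws$eps
  K <- length(model$batch_levels)
  unif <- matrix(1 / K, nrow(xb), K)
  # condition on the true one-hot label: the predicted probabilities would be
  # a continuous side-channel through which the encoder can smuggle biology
  # (and correction decodes with hard one-hot codes anyway)
  fwD1 <- mlp_forward(model$decoder, cbind(z, Y))
  fwD2 <- mlp_forward(model$decoder, cbind(z, unif))
  fwD3 <- mlp_forward(model$decoder, cbind(z, draws$rand_code))
  fwE2 <- encoder_forward(model, fwD1$out)
  fwD4 <- mlp_forward(model$decoder, cbind(draws$z_prior, draws$prior_code))
  fwC1 <- mlp_forward(model$disc, xb)
  fwC2 <- mlp_forward(model$disc, fwD1$out)
  fwC3 <- mlp_forward(model$disc, fwD4$out)
  # the auxiliary reads the posterior mean: reading the sampled z would let
  # the encoder hide batch information below the sampling noise while the
  # deterministic mean retains it
  fwA <- mlp_forward(model$aux, fwE$mu)
  list(fwE = fwE, z = z, sd_ = sd_, fwD1 = fwD1, fwD2 = fwD2, fwD3 = fwD3,
       fwD4 = fwD4, fwE2 = fwE2, fwC1 = fwC1, fwC2 = fwC2, fwC3 = fwC3,
       fwA = fwA, unif = unif)
}

gen_losses <- function(fw, xb, Y, cw) {
  p_real <- stats::plogis(fw$fwC1$out[, 1])
  p_recon <- stats::plogis(fw$fwC2$out[, 1])
  p_prior <- stats::plogis(fw$fwC3$out[, 1])
  list(
    rec = loss_reconstruction(xb, fw$fwD1$out),
    kl = loss_kl(fw$fwE$mu, exp(fw$fwE$logvar)),
    class = loss_cross_entropy(fw$fwE$y_hat, Y, cw),
    class_hat = loss_cross_entropy(fw$fwE2$y_hat, Y, cw),
    aux = loss_cross_entropy(softmax_rows(fw$fwA$out), Y, cw),
    proj = loss_projection(fw$fwD1$out, fw$fwD2$out, fw$fwD3$out),
    gan = loss_gan(p_real, p_recon, p_prior)$disc_loss
  )
}

d_cosine <- function(a, b) {
  # gradient of rowwise cos(a, b) w.r.t. a; zero-norm pairs get 0
  na <- sqrt(rowSums(a^2)); nb <- sqrt(rowSums(b^2))
  ok <- na > 0 & nb > 0
  cs <- numeric(nrow(a))
  cs[ok] <- rowSums(a * b)[ok] / (na[ok] * nb[ok])
  g <- a * 0
  g[ok, ] <- b[ok, , drop = FALSE] / (na[ok] * nb[ok]) -
    cs[ok] * a[ok, , drop = FALSE] / na[ok]^2
  g
}

weighted_softmax_ce_grad <- function(prob, Y, cw, n, weight_by = Y) {
  # d(mean weighted CE)/d logits; cells weighted by their true class
  g <- (prob - Y) / n
  if (!is.null(cw)) g <- g * cw[max.col(weight_by, ties.method = "first")]
  g
}

gen_backward <- function(model, fw, xb, Y, cw, coef) {
  # coef: list rec, alpha, rho, beta, mu, delta, gamma (normalization folded in)
  n <- nrow(xb)
  k <- model$latent_dim
  K <- length(model$batch_levels)
  x_hat <- fw$fwD1$out

  # --- gradient w.r.t. x_hat (identical for encoder and decoder objectives)
  d_xhat <- coef$rec * 2 * (x_hat - xb) / n

  # re-encoded classification (through the second encoder pass)
  d_logits2 <- coef$beta * weighted_softmax_ce_grad(fw$fwE2$y_hat, Y, cw, n)
  bE2 <- encoder_backward(model, fw$fwE2,
                          d_mu = fw$fwE2$mu * 0,
                          d_logvar = fw$fwE2$logvar * 0,
                          d_logits = d_logits2)
  d_xhat <- d_xhat + bE2$d_x

  # projection constraint (maximized: minus sign)
  d_xhat <- d_xhat - coef$mu / n *
    (d_cosine(x_hat, fw$fwD2$out) + d_cosine(x_hat, fw$fwD3$out))
  d_xavg <- -coef$mu / n * d_cosine(fw$fwD2$out, x_hat)
  d_xrand <- -coef$mu / n * d_cosine(fw$fwD3$out, x_hat)

  # adversarial GAN term through the reconstruction: -delta/3 * CE(fake|C(x_hat))
  p_recon <- stats::plogis(fw$fwC2$out[, 1])
  dC2 <- mlp_backward(model$disc, fw$fwC2,
                      matrix(-coef$delta * p_recon / (3 * n), n, 1))
  d_xhat <- d_xhat + dC2$d_input

  # prior-decode GAN term (decoder path only)
  p_prior <- stats::plogis(fw$fwC3$out[, 1])
  dC3 <- mlp_backward(model$disc, fw$fwC3,
                      matrix(-coef$delta * p_prior / (3 * n), n, 1))

  # --- decoder gradients
  bD1 <- mlp_backward(model$decoder, fw$fwD1, d_xhat)
  bD2 <- mlp_backward(model$decoder, fw$fwD2, d_xavg)
  bD3 <- mlp_backward(model$decoder, fw$fwD3, d_xrand)
  bD4 <- mlp_backward(model$decoder, fw$fwD4, dC3$d_input)
  dec_grads <- mlp_add_grads(mlp_add_grads(bD1$grads, bD2$grads),
                             mlp_add_grads(bD3$grads, bD4$grads))

  # --- encoder gradients
  dz <- bD1$d_input[, seq_len(k), drop = FALSE] +
    bD2$d_input[, seq_len(k), drop = FALSE] +
    bD3$d_input[, seq_len(k), drop = FALSE]

  # adversarial auxiliary term: -gamma * CE(A(z), y)
  # non-saturating surrogate for the adversarial term: the encoder minimizes
  # CE(A(mu), batch prior) rather than maximizing CE(A(mu), y). Same fixed
  # point (the auxiliary at chance level) but bounded — the encoder cannot
  # escape by inflating the latent scale — and the prior target is what the
  # auxiliary outputs on any batch-uninformative input, so the latent is not
  # geometrically crushed into a special region.
  pA <- softmax_rows(fw$fwA$out)
  U <- matrix(1 / K, n, K)
  d_logitsA <- coef$gamma * weighted_softmax_ce_grad(pA, U, cw, n, weight_by = Y)
  bA <- mlp_backward(model$aux, fw$fwA, d_logitsA)

  # reparameterization: z = mu + exp(0.5 logvar) * eps; the auxiliary path
  # feeds the mean directly
  d_mu <- dz + bA$d_input
  d_logvar <- dz * fw$eps_used * 0.5 * fw$sd_

  # KL closed form, with free bits: dimensions whose per-dimension KL is
  # below the floor are exempt from the pull to the prior, so a few nats of
  # information can never be squeezed out of the latent (the standard
  # posterior-collapse safeguard)
  sigma2 <- exp(fw$fwE$logvar)
  kl_dims <- colMeans(0.5 * (-fw$fwE$logvar - 1 + fw$fwE$mu^2 + sigma2))
  mask <- rep(as.numeric(kl_dims > coef$free_nats), each = n)
  d_mu <- d_mu + coef$alpha * mask * fw$fwE$mu / n
  d_logvar <- d_logvar + coef$alpha * mask * 0.5 * (sigma2 - 1) / n

  # classification head (decoder conditioning uses the constant one-hot label)
  d_logits <- coef$rho * weighted_softmax_ce_grad(fw$fwE$y_hat, Y, cw, n)

  bE1 <- encoder_backward(model, fw$fwE, d_mu, d_logvar, d_logits)
  enc_grads <- list(
    trunk = mlp_add_grads(bE1$trunk, bE2$trunk),
    head_mu = mlp_add_grads(bE1$head_mu, bE2$head_mu),
    head_logvar = mlp_add_grads(bE1$head_logvar, bE2$head_logvar),
    head_cls = mlp_add_grads(bE1$head_cls, bE2$head_cls)
  )
  list(enc_grads = enc_grads, dec_grads = dec_grads)
}

#' Train an AIF model
#'
#' Alternating optimization: per minibatch the discriminator is updated on its
#' real/fake loss, the auxiliary classifier on its batch-prediction loss, then
#' the decoder and encoder on their objectives (computed against the updated
#' adversaries). With `dyn = TRUE` each loss entering the encoder/decoder
#' objectives is divided by its dynamic normalizer — the trailing-window
#' median of its per-epoch values — recomputed once per epoch.
#'
#' @param dataset An `expr_dataset` with at least two batches.
#' @param model An [aif_model()] matching the dataset's gene dimension and
#'   batch vocabulary.
#' @param config A [train_config()].
#' @param dyn Logical; enable dynamic loss normalization (default TRUE).
#' @return A list with `model` (trained) and `report` (an `aif_loss_report`
#'   with per-epoch raw losses, normalizers, and objective values).
#' @export
train_aif <- function(dataset, model, config = train_config(), dyn = TRUE) {
  stopifnot(inherits(dataset, "expr_dataset"), inherits(model, "aif_model"))
  if (nlevels(dataset$batch) < 2) {
    stop("training requires at least two batches: nothing to factor out")
  }
  if (!identical(levels(dataset$batch), model$batch_levels)) {
    stop("model batch vocabulary does not match the dataset")
  }
  if (ncol(dataset$matrix) != model$n_genes) {
    stop("model gene dimension (", model$n_genes, ") does not match dataset (",
         ncol(dataset$matrix), ")")
  }
  n <- nrow(dataset$matrix)
  mb <- min(config$minibatch_size, n)
  X <- dataset$matrix
  Yf <- dataset$batch
  Y <- one_hot(Yf)
  K <- nlevels(Yf)
  k <- model$latent_dim
  cw <- if (config$class_weights == "inverse_frequency") {
    batch_class_weights(Yf)
  } else NULL
  batch_freq <- tabulate(Yf, K) / n

  report <- new_loss_report(config$epochs)
  if (config$epochs == 0) {
    return(list(model = model, report = report))
  }

  set.seed(config$seed)
  opt <- list(
    trunk = adam_init(model$trunk), head_mu = adam_init(model$head_mu),
    head_logvar = adam_init(model$head_logvar),
    head_cls = adam_init(model$head_cls),
    decoder = adam_init(model$decoder), disc = adam_init(model$disc),
    aux = adam_init(model$aux)
  )
  w <- config$weights
  gen_blocks <- c("trunk", "head_mu", "head_logvar", "head_cls", "decoder")
  ema <- if (!is.null(config$ema_decay)) model[gen_blocks]

  # with dyn, the first epoch's normalizers come from a pre-training forward
  # pass so the gradient scale is consistent from the first step (the Adam
  # second moment would otherwise remember the unnormalized scale for ~1/(1-b2)
  # steps and stall the run)
  norms0 <- rep(1, length(LOSS_NAMES)); names(norms0) <- LOSS_NAMES
  if (dyn) {
    idx0 <- seq_len(min(mb, n))
    draws0 <- list(
      eps = matrix(stats::rnorm(length(idx0) * k), length(idx0), k),
      rand_code = one_hot(factor(sample(model$batch_levels, length(idx0),
                                        replace = TRUE),
                                 levels = model$batch_levels)),
      z_prior = matrix(stats::rnorm(length(idx0) * k), length(idx0), k),
      prior_code = one_hot(factor(sample(model$batch_levels, length(idx0),
                                         replace = TRUE, prob = batch_freq),
                                  levels = model$batch_levels)))
    fw0 <- gen_forward(model, X[idx0, , drop = FALSE], Y[idx0, , drop = FALSE],
                       draws0)
    norms0 <- pmax(abs(unlist(gen_losses(fw0, X[idx0, , drop = FALSE],
                                         Y[idx0, , drop = FALSE], cw))), 1e-2)
  }

  for (epoch in seq_len(config$epochs)) {
    adv_on <- epoch > config$adversarial_delay_epochs
    norms <- norms0
    if (dyn && epoch > 1) {
      norms <- dynamic_normalizers(report$losses[seq_len(epoch - 1), , drop = FALSE],
                                   epoch - 1, config$epochs,
                                   config$dyn_window_frac)
      # keep each normalizer within a band around the initial loss scale: a
      # collapsed loss (saturated discriminator, vanished KL) would otherwise
      # be amplified without bound, and an exploding one would lose all
      # restraint — both are absorbing states of the raw median scheme
      norms <- pmin(pmax(norms, 0.02 * norms0), 50 * norms0)
    }
    coef <- list(rec = 1 / norms[["rec"]], alpha = w$alpha / norms[["kl"]],
                 rho = w$rho / norms[["class"]],
                 beta = w$beta / norms[["class_hat"]],
                 mu = w$mu / norms[["proj"]],
                 delta = if (adv_on) w$delta / norms[["gan"]] else 0,
                 gamma = if (adv_on) w$gamma / norms[["aux"]] else 0,
                 free_nats = config$kl_free_nats)

    ord <- sample.int(n)
    starts <- seq(1, n, by = mb)
    acc <- numeric(length(LOSS_NAMES)); names(acc) <- LOSS_NAMES
    n_steps <- 0L

    for (s in starts) {
      idx <- ord[s:min(s + mb - 1L, n)]
      nb <- length(idx)
      xb <- X[idx, , drop = FALSE]
      Yb <- Y[idx, , drop = FALSE]

      draws <- list(
        eps = matrix(stats::rnorm(nb * k), nb, k),
        rand_code = one_hot(factor(sample(model$batch_levels, nb, replace = TRUE),
                                   levels = model$batch_levels)),
        z_prior = matrix(stats::rnorm(nb * k), nb, k),
        prior_code = one_hot(factor(sample(model$batch_levels, nb, replace = TRUE,
                                           prob = batch_freq),
                                    levels = model$batch_levels))
      )

      fw <- gen_forward(model, xb, Yb, draws)
      fw$eps_used <- draws$eps

      # (1) discriminator on its real/fake loss
      if (adv_on) {
        p1 <- stats::plogis(fw$fwC1$out[, 1])
        p2 <- stats::plogis(fw$fwC2$out[, 1])
        p3 <- stats::plogis(fw$fwC3$out[, 1])
        gC <- mlp_add_grads(
          mlp_backward(model$disc, fw$fwC1, matrix((p1 - 1) / (3 * nb), nb, 1))$grads,
          mlp_add_grads(
            mlp_backward(model$disc, fw$fwC2, matrix(p2 / (3 * nb), nb, 1))$grads,
            mlp_backward(model$disc, fw$fwC3, matrix(p3 / (3 * nb), nb, 1))$grads))
        st <- adam_step(model$disc, gC, opt$disc, config$lr_disc)
        model$disc <- st$net; opt$disc <- st$opt

        # (2) auxiliary on its batch-prediction loss
        pA <- softmax_rows(fw$fwA$out)
        gA <- mlp_backward(model$aux, fw$fwA,
                           weighted_softmax_ce_grad(pA, Yb, cw, nb))$grads
        st <- adam_step(model$aux, gA, opt$aux, config$lr_aux)
        model$aux <- st$net; opt$aux <- st$opt

        # refresh adversary outputs for the generator losses/gradients
        fw$fwC1 <- mlp_forward(model$disc, xb)
        fw$fwC2 <- mlp_forward(model$disc, fw$fwD1$out)
        fw$fwC3 <- mlp_forward(model$disc, fw$fwD4$out)
        fw$fwA <- mlp_forward(model$aux, fw$fwE$mu)
      }

      losses <- gen_losses(fw, xb, Yb, cw)
      bad <- names(losses)[!vapply(losses, is.finite, logical(1))]
      if (length(bad)) {
        stop("non-finite loss term at epoch ", epoch, ": ",
             paste(bad, collapse = ", "))
      }

      # (3) decoder, (4) encoder — gradients from one pass, applied in order
      gr <- gen_backward(model, fw, xb, Yb, cw, coef)
      st <- adam_step(model$decoder, gr$dec_grads, opt$decoder, config$lr_decoder)
      model$decoder <- st$net; opt$decoder <- st$opt
      for (blk in c("trunk", "head_mu", "head_logvar", "head_cls")) {
        st <- adam_step(model[[blk]], gr$enc_grads[[blk]], opt[[blk]],
                        config$lr_encoder)
        model[[blk]] <- st$net; opt[[blk]] <- st$opt
      }

      acc <- acc + unlist(losses)
      n_steps <- n_steps + 1L
    }

    if (!is.null(config$ema_decay)) {
      d <- config$ema_decay
      if (epoch <= config$adversarial_delay_epochs) {
        ema <- model[gen_blocks]   # track exactly until the adversaries start
      } else {
        for (blk in gen_blocks) {
          for (li in seq_along(ema[[blk]]$layers)) {
            ema[[blk]]$layers[[li]]$W <- d * ema[[blk]]$layers[[li]]$W +
              (1 - d) * model[[blk]]$layers[[li]]$W
            ema[[blk]]$layers[[li]]$b <- d * ema[[blk]]$layers[[li]]$b +
              (1 - d) * model[[blk]]$layers[[li]]$b
          }
        }
      }
    }

    epoch_losses <- acc / n_steps
    report$losses[epoch, ] <- epoch_losses
    report$normalizers[epoch, ] <- norms
    ln <- as.list(epoch_losses / norms)
    report$enc_objective[epoch] <- encoder_objective(ln, w)
    report$dec_objective[epoch] <- decoder_objective(ln, w)
    report$epochs_completed <- epoch
  }
  if (!is.null(config$ema_decay)) model[gen_blocks] <- ema
  list(model = model, report = report)
}

new_loss_report <- function(epochs) {
  m <- matrix(NA_real_, epochs, length(LOSS_NAMES),
              dimnames = list(NULL, LOSS_NAMES))
  structure(list(losses = m, normalizers = m,
                 enc_objective = rep(NA_real_, epochs),
                 dec_objective = rep(NA_real_, epochs),
                 epochs_completed = 0L),
            class = "aif_loss_report")
}

#' @export
print.aif_loss_report <- function(x, ...) {
  cat(sprintf("<aif_loss_report> %d epochs completed\n", x$epochs_completed))
  if (x$epochs_completed > 0) {
    last <- x$losses[x$epochs_completed, ]
    cat("  final losses:",
        paste(sprintf("%s=%.4g", names(last), last), collapse = ", "), "\n")
  }
  invisible(x)
}
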