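test_that("reconstruction loss: zero at equality, hand value, homogeneity", {
  x <- rbind(c(0, 0), c(1, 2))
  expect_identical(loss_reconstruction(x, x), 0)
  expect_equal(loss_reconstruction(rbind(c(0, 0)), rbind(c(1, 1))), 2)
  xh <- x + 0.3
  expect_equal(loss_reconstruction(x, x + 3 * 0.3),
               9 * loss_reconstruction(x, xh), tolerance = 1e-12)
})

test_that("KL loss matches the closed form and a Monte-Carlo oracle", {
  # prior equals posterior
  expect_equal(loss_kl(rbind(c(0, 0)), rbind(c(1, 1))), 0)
  # hand substitution: k = 2, mu = (1, 0), Sigma = I -> 1/2
  expect_equal(loss_kl(rbind(c(1, 0)), rbind(c(1, 1))), 0.5)
  expect_error(loss_kl(rbind(0), rbind(-1)), "positive")

  # Monte-Carlo KL estimator: E_q[log q(z) - log p(z)] over 20 random draws
  set.seed(11)
  n_mc <- 40000
  for (i in 1:20) {
    k <- sample(1:4, 1)
    mu <- rnorm(k, sd = 1.5)
    s2 <- exp(rnorm(k, sd = 0.7))
    z <- matrix(rnorm(n_mc * k), n_mc, k) * rep(sqrt(s2), each = n_mc) +
      rep(mu, each = n_mc)
    log_q <- rowSums(dnorm(z, rep(mu, each = n_mc), rep(sqrt(s2), each = n_mc),
                           log = TRUE))
    log_p <- rowSums(dnorm(z, log = TRUE))
    diff <- log_q - log_p
    se <- sd(diff) / sqrt(n_mc)
    expect_lt(abs(mean(diff) - loss_kl(rbind(mu), rbind(s2))), 3 * se + 1e-9)
  }

  # non-negativity on random parameters
  set.seed(12)
  for (i in 1:25) {
    expect_gte(loss_kl(rbind(rnorm(3)), rbind(exp(rnorm(3)))), 0)
  }
})

test_that("cross-entropy: perfect, hand value, weighting", {
  one <- rbind(c(1, 0))
  expect_lt(loss_cross_entropy(one, one), 1e-6)            # at the clamp floor
  expect_equal(loss_cross_entropy(rbind(c(0.5, 0.5)), rbind(c(0, 1))),
               -log(0.5), tolerance = 1e-9)
  # balanced class weights reproduce the unweighted value
  p <- rbind(c(0.7, 0.3), c(0.2, 0.8))
  t2 <- rbind(c(1, 0), c(0, 1))
  expect_equal(loss_cross_entropy(p, t2, class_weights = c(1, 1)),
               loss_cross_entropy(p, t2))
  # saturated predictions stay finite
  expect_true(is.finite(loss_cross_entropy(rbind(c(1, 0)), rbind(c(0, 1)))))
})

test_that("inverse-frequency class weights have mean one", {
  w <- batch_class_weights(factor(c("a", "a", "a", "b")))
  expect_equal(mean(w), 1)
  expect_gt(w[2], w[1])
})

test_that("projection constraint: self-similarity 2, orthogonal 0, zero-norm 0", {
  a <- rbind(c(1, 2, 3), c(2, 0, 1))
  expect_equal(loss_projection(a, a, a), 2)
  x <- rbind(c(1, 0)); y <- rbind(c(0, 1))
  expect_equal(loss_projection(x, y, y), 0)
  z <- rbind(c(0, 0))
  expect_equal(loss_projection(z, x, y), 0)  # zero-norm pairs contribute 0
})

test_that("GAN loss: indifferent discriminator gives -log 0.5, perfect gives ~0", {
  half <- rep(0.5, 4)
  g <- loss_gan(half, half, half)
  expect_equal(g$disc_loss, -log(0.5), tolerance = 1e-12)
  expect_identical(g$disc_loss, g$adv_term)  # same forward pass, same value
  perf <- loss_gan(rep(1, 4), rep(0, 4), rep(0, 4))
  expect_lt(perf$disc_loss, 1e-6)
})

test_that("encode returns strictly positive variances and preserves order", {
  m <- tiny_model(d = 6, k = 3)
  set.seed(1)
  X <- matrix(rnorm(30), 5, 6)
  enc <- aif_encode(m, X)
  expect_true(all(enc$sigma2 > 0))
  expect_identical(dim(enc$mu), c(5L, 3L))
  expect_equal(rowSums(enc$y_hat), rep(1, 5), tolerance = 1e-9)
  # order-preserving and deterministic
  enc2 <- aif_encode(m, X[c(3, 1), ])
  expect_equal(enc2$mu, enc$mu[c(3, 1), ], tolerance = 1e-12)
  expect_identical(aif_encode(m, X)$mu, enc$mu)
  expect_error(aif_encode(m, matrix(0, 2, 4)), "expected 6 genes")
})

test_that("sample_latent implements the reparameterization", {
  mu <- rbind(c(1, -2), c(0, 3))
  # zero-variance limit returns the mean
  expect_equal(sample_latent(mu, mu * 0, seed = 1)$z, mu)
  # same seed, same draw
  s2 <- rbind(c(1, 2), c(0.5, 1))
  expect_identical(sample_latent(mu, s2, seed = 5)$z,
                   sample_latent(mu, s2, seed = 5)$z)
  # the sample mean approaches mu at the Monte-Carlo rate
  n <- 10000
  zs <- sample_latent(matrix(1, n, 1), matrix(4, n, 1), seed = 2)$z
  expect_lt(abs(mean(zs) - 1), 4 * 2 / sqrt(n))
  expect_error(sample_latent(mu, -s2), "non-negative")
})

test_that("decode is conditional on the batch code and deterministic", {
  m <- tiny_model(d = 6, k = 3)
  z <- matrix(rnorm(9), 3, 3)
  xa <- aif_decode(m, z, c(1, 0))
  xb <- aif_decode(m, z, c(0.5, 0.5))
  expect_identical(dim(xa), c(3L, 6L))
  expect_false(isTRUE(all.equal(xa, xb)))        # conditionality exercised
  expect_identical(aif_decode(m, z, c(1, 0)), xa)  # deterministic
  expect_error(aif_decode(m, z, c(2, -1)), "\\[0, 1\\]")
})

test_that("loss definitions are architecture-independent (widths 16 and 128)", {
  set.seed(3)
  X <- matrix(rnorm(4 * 10), 4, 10)
  for (w in c(16, 128)) {
    m <- aif_model(10, c("A", "B"), latent_dim = 5, hidden = c(w, w),
                   disc_hidden = c(8), aux_hidden = c(8), seed = 1)
    enc <- aif_encode(m, X)
    xh <- aif_decode(m, enc$mu, c(1, 0))
    expect_identical(dim(xh), dim(X))
    expect_gte(loss_kl(enc$mu, enc$sigma2), 0)
    expect_gte(loss_reconstruction(X, xh), 0)
  }
})

test_that("re-encoded classification loss behaves at its limits", {
  set.seed(4)
  xh <- matrix(rnorm(24), 4, 6)
  y <- factor(c("A", "B", "A", "B"), levels = c("A", "B"))
  m0 <- tiny_model(d = 6, k = 3)
  l0 <- reencode_class_loss(m0, xh, y)
  expect_true(is.finite(l0) && l0 >= 0)
  # an encoder that predicts uniformly scores exactly -log 0.5
  L <- length(m0$head_cls$layers)
  m0$head_cls$layers[[L]]$W[] <- 0
  m0$head_cls$layers[[L]]$b[] <- 0
  expect_equal(reencode_class_loss(m0, xh, y), -log(0.5), tolerance = 1e-9)
})

test_that("analytic gradients match finite differences on every path", {
  ns <- asNamespace("scaif")
  set.seed(42)
  n <- 7; d <- 11; k <- 3
  model <- aif_model(d, c("A", "B"), latent_dim = k, hidden = c(8, 6),
                     disc_hidden = c(5), aux_hidden = c(4), seed = 3)
  xb <- matrix(rnorm(n * d, sd = 0.2), n, d)  # small scale: no clamp saturation
  Yf <- factor(c("A", "B", "A", "B", "A", "B", "A"), levels = c("A", "B"))
  Y <- ns$one_hot(Yf)
  cw <- batch_class_weights(Yf)
  draws <- list(
    eps = matrix(rnorm(n * k), n, k),
    rand_code = ns$one_hot(factor(sample(c("A", "B"), n, TRUE),
                                  levels = c("A", "B"))),
    z_prior = matrix(rnorm(n * k), n, k),
    prior_code = ns$one_hot(factor(sample(c("A", "B"), n, TRUE),
                                   levels = c("A", "B"))))
  coef <- list(rec = 0.7, alpha = 1.3, rho = 0.9, beta = 1.1, mu = 0.8,
               delta = 0.6, gamma = 0, free_nats = 0)
  w <- list(alpha = coef$alpha / coef$rec, rho = coef$rho / coef$rec,
            beta = coef$beta / coef$rec, mu = coef$mu / coef$rec,
            delta = coef$delta / coef$rec, gamma = 0)
  obj <- function(m) {
    fw <- ns$gen_forward(m, xb, Y, draws)
    fw$eps_used <- draws$eps
    coef$rec * encoder_objective(ns$gen_losses(fw, xb, Y, cw), w)
  }
  fw <- ns$gen_forward(model, xb, Y, draws)
  fw$eps_used <- draws$eps
  gr <- ns$gen_backward(model, fw, xb, Y, cw, coef)
  h <- 1e-5
  for (blk in c("trunk", "head_mu", "head_logvar", "head_cls")) {
    g <- gr$enc_grads[[blk]][[1]]$W
    for (idx in list(c(1, 1), c(2, 1))) {
      m1 <- model; m2 <- model
      m1[[blk]]$layers[[1]]$W[idx[1], idx[2]] <-
        m1[[blk]]$layers[[1]]$W[idx[1], idx[2]] + h
      m2[[blk]]$layers[[1]]$W[idx[1], idx[2]] <-
        m2[[blk]]$layers[[1]]$W[idx[1], idx[2]] - h
      num <- (obj(m1) - obj(m2)) / (2 * h)
      expect_equal(unname(g[idx[1], idx[2]]), num, tolerance = 1e-5,
                   info = paste("encoder block", blk))
    }
  }
  objd <- function(m) {
    fw <- ns$gen_forward(m, xb, Y, draws)
    fw$eps_used <- draws$eps
    coef$rec * decoder_objective(ns$gen_losses(fw, xb, Y, cw), w)
  }
  g <- gr$dec_grads[[1]]$W
  for (idx in list(c(1, 2), c(3, 1))) {
    m1 <- model; m2 <- model
    m1$decoder$layers[[1]]$W[idx[1], idx[2]] <-
      m1$decoder$layers[[1]]$W[idx[1], idx[2]] + h
    m2$decoder$layers[[1]]$W[idx[1], idx[2]] <-
      m2$decoder$layers[[1]]$W[idx[1], idx[2]] - h
    num <- (objd(m1) - objd(m2)) / (2 * h)
    expect_equal(unname(g[idx[1], idx[2]]), num, tolerance = 1e-5, info = "decoder")
  }
})
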