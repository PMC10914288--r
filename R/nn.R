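# Minimal dense-network machinery: fully connected stacks with leaky-rectifier
# activations, reverse-mode gradients written out by hand, and Adam updates.
# All forward passes operate on n x p row-major minibatches via BLAS matmuls.

LRELU_SLOPE <- 0.2

mlp_init <- function(sizes, final_linear = TRUE) {
  # He-style initialization; `sizes` includes input and output dims
  layers <- vector("list", length(sizes) - 1L)
  for (i in seq_along(layers)) {
    fan_in <- sizes[i]
    layers[[i]] <- list(
      W = matrix(stats::rnorm(fan_in * sizes[i + 1], sd = sqrt(2 / fan_in)),
                 fan_in, sizes[i + 1]),
      b = numeric(sizes[i + 1])
    )
  }
  structure(list(layers = layers, final_linear = final_linear), class = "mlp")
}

mlp_forward <- function(net, X) {
  L <- length(net$layers)
  pre <- vector("list", L)   # pre-activations
  act <- vector("list", L + 1L)
  act[[1]] <- X
  for (i in seq_len(L)) {
    z <- act[[i]] %*% net$layers[[i]]$W
    z <- sweep(z, 2, net$layers[[i]]$b, "+")
    pre[[i]] <- z
    if (i < L || !net$final_linear) {
      z <- ifelse(z > 0, z, LRELU_SLOPE * z)
    }
    act[[i + 1]] <- z
  }
  list(out = act[[L + 1]], pre = pre, act = act)
}

mlp_backward <- function(net, cache, d_out) {
  # returns parameter gradients and the gradient w.r.t. the input
  L <- length(net$layers)
  grads <- vector("list", L)
  delta <- d_out
  for (i in rev(seq_len(L))) {
    if (i < L || !net$final_linear) {
      delta <- delta * ifelse(cache$pre[[i]] > 0, 1, LRELU_SLOPE)
    }
    grads[[i]] <- list(W = crossprod(cache$act[[i]], delta),
                       b = colSums(delta))
    delta <- tcrossprod(delta, net$layers[[i]]$W)
  }
  list(grads = grads, d_input = delta)
}

mlp_add_grads <- function(g1, g2) {
  if (is.null(g1)) return(g2)
  for (i in seq_along(g1)) {
    g1[[i]]$W <- g1[[i]]$W + g2[[i]]$W
    g1[[i]]$b <- g1[[i]]$b + g2[[i]]$b
  }
  g1
}

adam_init <- function(net) {
  state <- lapply(net$layers, function(l) {
    list(mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0)
  })
  list(t = 0L, state = state)
}

adam_step <- function(net, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (i in seq_along(net$layers)) {
    s <- opt$state[[i]]
    g <- grads[[i]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$W
    s$vW <- beta2 * s$vW + (1 - beta2) * g$W^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$b
    s$vb <- beta2 * s$vb + (1 - beta2) * g$b^2
    net$layers[[i]]$W <- net$layers[[i]]$W -
      lr * (s$mW / bc1) / (sqrt(s$vW / bc2) + eps)
    net$layers[[i]]$b <- net$layers[[i]]$b -
      lr * (s$mb / bc1) / (sqrt(s$vb / bc2) + eps)
    opt$state[[i]] <- s
  }
  list(net = net, opt = opt)
}

softmax_rows <- function(logits) {
  z <- logits - apply(logits, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

PROB_FLOOR <- 1e-7

clamp_prob <- function(p) pmin(pmax(p, PROB_FLOOR), 1 - PROB_FLOOR)
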