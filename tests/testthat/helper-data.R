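# small builders used across test files

tiny_dataset <- function(n = 6, d = 4, batches = c("b1", "b2"), seed = 1) {
  set.seed(seed)
  m <- matrix(rpois(n * d, 5), n, d)
  expression_dataset(m, batch = rep(batches, length.out = n),
                     cell_type = rep_len(rep(c("t1", "t2"), each = ceiling(n / 2)), n),
                     space = "raw")
}

two_blob_embedding <- function(n_per = 20, sep = 10, seed = 1) {
  set.seed(seed)
  rbind(matrix(rnorm(2 * n_per, 0, 0.3), ncol = 2),
        matrix(rnorm(2 * n_per, sep, 0.3), ncol = 2))
}

tiny_model <- function(d = 6, k = 3, levels = c("A", "B"), seed = 2) {
  aif_model(d, levels, latent_dim = k, hidden = c(8, 6), disc_hidden = c(5),
            aux_hidden = c(4), seed = seed)
}
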