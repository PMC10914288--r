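# the trained strong-batch benchmark is expensive; build it once per session
# and share it across the acceptance tests
.benchmark_cache <- new.env(parent = emptyenv())

benchmark_fixture <- function() {
  if (is.null(.benchmark_cache$bench)) {
    .benchmark_cache$bench <- run_strong_batch_benchmark(seed = 42L)
  }
  .benchmark_cache$bench
}
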