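# Shared fixtures for the test suite.  Everything is built in code; the one
# expensive object (a trained 6-neuron A3 network) is trained once per test
# run and cached.

.test_cache <- new.env(parent = emptyenv())

# A 6-neuron configuration: inputs 1,2; outputs 3,4; hidden 5,6 (K = 2).
test_config6 <- function() network_config(6)

# Deterministic small random weights.
test_weights <- function(n = 6, seed = 42, scale = 0.5) {
  set.seed(seed)
  weight_matrix(matrix(runif(n * n, -scale, scale), n, n))
}

# Short training configuration for smoke tests.
test_train_cfg <- function(max_generations = 5000L, ...) {
  train_config(stream = stream_config(length_symbols = 30L, rng_seed = 7L),
               max_generations = max_generations, ...)
}

# A 6-neuron network trained to zero errors on A3 (cached across tests).
trained_a3 <- function() {
  if (is.null(.test_cache$a3)) {
    cfg <- train_config(max_generations = 20000L)
    res <- evolve_restarts(test_config6(), task_spec("A3"), cfg,
                           max_attempts = 10L, base_seed = 11L)
    stopifnot(res$success)
    .test_cache$a3 <- res
  }
  .test_cache$a3
}
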