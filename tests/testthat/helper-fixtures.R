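# Shared small fixtures and a desk-scale training configuration.

tiny_samples <- function(n = 2, size = 32, seed = 101, ...) {
  generate_fixtures(fixture_spec(n_samples = n, size = size, seed = seed, ...))
}

# smallest model that exercises every component
tiny_config <- function(...) {
  mfel_config(epochs = 4, batch_size = 2, working_size = 32,
              stage_channels = c(4L, 8L, 8L), state_dim = 4L,
              warmup_epochs = 1, seed = 7, ...)
}

tiny_model <- function(config = tiny_config()) {
  set.seed(config$seed)
  mfel_model(config)
}

random_binary_mask <- function(h, w, p = 0.4) {
  array(stats::rbinom(h * w, 1, p), c(1, h, w))
}
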