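# Shared (memoised) training runs. The full ablation study and the small
# 50-image sanity fit are each computed once per test session and reused by
# every test that needs them.

.run_cache <- new.env(parent = emptyenv())

# Desk-scale ablation study: 200 train / 10 val / 30 test synthetic 32 px
# cells, width-32 SR nets (prior base 16), scale 4, 40 epochs.
get_ablation_study <- function() {
  if (is.null(.run_cache$study))
    .run_cache$study <- run_ablation(seed = 42L)
  .run_cache$study
}

# Small sanity fit: geometry-prior on 50 training images, 10 epochs.
get_small_fit <- function() {
  if (is.null(.run_cache$small)) {
    ds <- generate_dataset(60, split = c(50 / 60, 4 / 60, 6 / 60), seed = 5,
                           image_size = 32, texture_amplitude = 0.08,
                           blur_sigma = 0.5)
    fit <- leukosr_fit(ds, scale = 4, variant = "geometry-prior",
                       train = train_config(batch_size = 8,
                                            learning_rate = 1e-3,
                                            epochs = 10, seed = 5),
                       prior = prior_net_config(base_width = 16, depth = 4),
                       sr = sr_net_config(feature_width = 32))
    .run_cache$small <- list(ds = ds, fit = fit)
  }
  .run_cache$small
}

# Tiny dataset for fast training-mechanics tests.
tiny_dataset <- function(n = 16, seed = 9, image_size = 32) {
  generate_dataset(n, split = c(0.75, 0.125, 0.125), seed = seed,
                   image_size = image_size)
}

tiny_train_cfg <- function(epochs = 2, seed = 3, lr = 1e-3) {
  train_config(batch_size = 4, learning_rate = lr, epochs = epochs, seed = seed)
}

tiny_net_cfgs <- function() {
  list(prior = prior_net_config(base_width = 4, depth = 2),
       sr = sr_net_config(feature_width = 8))
}
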