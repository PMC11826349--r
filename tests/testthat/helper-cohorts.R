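# Small-scale synthetic settings used across tests: 16-node connectomes train
# in seconds while keeping the full two-site structure (site, age, sex,
# noise) of the generator.

tiny_generator <- function(n_per_site = 24, seed = 11, ...) {
  generator_config(n_nodes = 16, n_per_site = n_per_site, seed = seed, ...)
}

tiny_vae_config <- function(epochs = 40, seed = 3, ...) {
  vae_config(input_dim = 16 * 15 / 2, n_sites = 2, hidden_dim = 48,
             latent_dim = 8, batch_size = 16, epochs = epochs,
             kl_warmup = 10, seed = seed, ...)
}

# memoized tiny trained model shared by harmonization/evaluation tests
.test_cache <- new.env(parent = emptyenv())

tiny_trained <- function() {
  if (!is.null(.test_cache$tiny)) return(.test_cache$tiny)
  gcfg <- tiny_generator()
  gen <- generate_cohort(gcfg)
  meas <- measures_table(gen$cohort)
  model <- vae_train(gen$cohort, meas, tiny_vae_config())
  test <- generate_matched_testset(gcfg, 12)
  .test_cache$tiny <- list(gcfg = gcfg, gen = gen, meas = meas,
                           model = model, test = test)
  .test_cache$tiny
}
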