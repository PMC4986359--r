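# Shared fixtures: small, fast synthetic sessions for the unit tests.
# The full-protocol configuration is exercised in test-acceptance.R.

tiny_config <- function(seed = 1L, ...) {
  args <- list(n_channels = 5L, sample_rate = 200, n_classes = 4L,
               n_true_synergies = 3L, trial_duration = 1.5,
               rest_duration = 0.5, reps_train = 4L, reps_test = 5L,
               noise_sd = 0.01, rep_variability = 0.05, seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(synth_config, args)
}

tiny_session <- function(seed = 1L, phase = "training", ...) {
  cfg <- tiny_config(seed = seed, ...)
  truth <- make_ground_truth(cfg)
  list(config = cfg, truth = truth,
       session = generate_session(cfg, truth, phase))
}

tiny_spec <- function() window_spec(window = 40L, step = 5L)

# Separable two-cluster feature set for classifier tests.
blob_features <- function(n_per = 30L, dim = 4L, gap = 4, seed = 1L) {
  set.seed(seed)
  x1 <- matrix(rnorm(n_per * dim), n_per, dim)
  x2 <- matrix(rnorm(n_per * dim), n_per, dim) + gap
  list(X = rbind(x1, x2),
       labels = rep(c("a", "b"), each = n_per))
}
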