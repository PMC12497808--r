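# Shared fixtures: everything is generated in code, nothing is stored.

# small but non-degenerate network configuration for structural tests
tiny_model_config <- function(C = 4, T_samples = 256, n_classes = 2,
                              dropout = 0.3) {
  model_config(C = C, T_samples = T_samples, n_classes = n_classes,
               F1 = 8, D = 2, n_heads = 4, ffn_hidden = 32, r = 4,
               dropout = dropout)
}

# small synthetic family matching tiny_model_config geometry
tiny_synth_config <- function(seed = 1, n_trials_per_class = 30,
                              erd_depth = 0.8, ...) {
  synth_config(n_trials_per_class = n_trials_per_class, n_channels = 4,
               n_samples = 256, fs = 250, erd_depth = erd_depth,
               erd_window = 65:192, seed = seed, ...)
}

# an easier variant of the tiny family (stronger rhythm, wider ERD window)
# for tests that need above-chance learning within seconds
easy_synth_config <- function(seed = 1, n_trials_per_class = 25) {
  synth_config(n_trials_per_class = n_trials_per_class, n_channels = 4,
               n_samples = 256, fs = 250, erd_depth = 0.8, mu_amp = 4,
               erd_window = 33:224, seed = seed)
}

random_epochs <- function(n = 6, C = 4, T = 256, K = 2, fs = 250, seed = 1) {
  set.seed(seed)
  eeg_epochs(array(rnorm(n * C * T), c(n, C, T)),
             rep_len(0:(K - 1), n), fs)
}

# session-level cache so expensive fixtures are built once per test run
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, .fixture_cache)) assign(key, builder(), .fixture_cache)
  get(key, .fixture_cache)
}

# the reference study conditions: two-class ERD data at full trial length
# (22-channel montage scaled to 8 channels), model trained 50 epochs
acceptance_fixture <- function() {
  cached("acceptance", function() {
    tr <- synth_epochs(synth_config(seed = 11), "train")
    te <- synth_epochs(synth_config(seed = 12), "test")
    model <- build_model(model_config(C = 8, T_samples = 1000, n_classes = 2),
                         seed = 0)
    model <- train(model, tr, train_config(epochs = 50, seed = 0))
    list(model = model, train = tr, test = te,
         scfg = synth_config(seed = 11))
  })
}
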