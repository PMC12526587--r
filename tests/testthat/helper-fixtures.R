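# Shared fixtures: tiny network configs and small synthetic inputs, all
# generated in code at test time.

tiny_net <- function(input_len = 40L, feature_dim = 6L, dropout = 0) {
  net_config(input_len, patch = 8L, stride = 8L, d_model = 8L, n_heads = 2L,
             n_layers = 2L, ffn_dim = 12L, conv_kernels = c(3L, 5L, 7L),
             conv_channels = 3L, feature_dim = feature_dim, disc_hidden = 5L,
             dropout = dropout)
}

tiny_bundle <- function(seed = 7L, n_classes = 2L, ...) {
  cfg <- tiny_net(...)
  model_bundle(cfg$input_len, n_classes, config = cfg, seed = seed)
}

# A small labeled dataset with a linearly separable class signal.
tiny_dataset <- function(n = 20L, len = 40L, seed = 1L, domain = "source",
                         effect = 1) {
  withr_seed <- function(expr) { set.seed(seed); expr }
  withr_seed({
    grid <- seq(500, 1500, length.out = len)
    y <- rep(0:1, length.out = n)
    X <- matrix(runif(n * len, 0, 0.2), n, len)
    bump <- exp(-(grid - 1000)^2 / (2 * 40^2))
    X <- X + outer(y * effect, bump)
    spectral_dataset(X, y = y, wavenumbers = grid, domain = domain)
  })
}

# A minimal two-domain pair on a short grid, preprocessed and balanced,
# cheap enough for training smoke tests.
tiny_pair <- function(seed = 1L, n_grid = 80L, smote = 24L) {
  grid <- default_grid(n_grid, 500, 2000)
  peaks <- list(peak_spec(700, 30, 0.8, 0), peak_spec(1000, 25, 0.5, 0.6),
                peak_spec(1500, 35, 0.6, 0.3))
  src <- generate_domain(c(healthy = 16L, disease = 16L), peaks,
                         domain_shift_spec(c(0.2, 0.1, 0, 0), 1, 0.02, 1,
                                           seed = seed),
                         grid, domain = "source")
  tgt <- generate_domain(c(healthy = 16L, disease = 16L), peaks,
                         domain_shift_spec(c(0.5, -0.2, 0.1, 0), 1.2, 0.03, 1,
                                           seed = seed + 1L,
                                           peak_response = c(1.2, 0.9, 0.8)),
                         grid, domain = "target")
  set.seed(seed + 2L)
  si <- sample(nrow(src$X), 24L); ti <- sample(nrow(tgt$X), 24L)
  source_train <- cd$subset_dataset(src, sort(si))
  source_test <- cd$subset_dataset(src, setdiff(seq_len(nrow(src$X)), sort(si)))
  target_train <- cd$subset_dataset(tgt, sort(ti))
  target_test <- cd$subset_dataset(tgt, setdiff(seq_len(nrow(tgt$X)), sort(ti)))
  sealed <- list(train = target_train$y, test = target_test$y)
  target_train$y <- NULL; target_test$y <- NULL
  pair <- domain_pair(source_train, source_test, target_train, target_test,
                      sealed)
  prepare_pair(pair, smote_count = smote, k_neighbors = 3L, seed = seed)
}

# Access to internals under test (not part of the public surface).
cd <- asNamespace("cdanpl")
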