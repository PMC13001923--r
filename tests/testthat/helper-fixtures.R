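# Shared fixtures: everything is generated in code at test time.

# A small non-negative view with reproducible values.
tiny_view <- function(n = 8, p = 5, seed = 42, modality = "toy") {
  set.seed(seed)
  omics_view(matrix(abs(rnorm(n * p)), n, p), modality = modality)
}

# A small but trainable multi-omics dataset.
tiny_dataset <- function(n = 24, n_classes = 2, seed = 7, noise_sd = 0.2,
                         views = c(a = 12, b = 10)) {
  generate_multiomics(synthetic_spec(
    n_samples = n, n_classes = n_classes, views = views,
    signal_strength = 4, scale_jitter_sd = 0.3, noise_sd = noise_sd,
    class_proportions = rep(1 / n_classes, n_classes), seed = seed))
}

# A fast training configuration for plumbing tests.
fast_config <- function(...) {
  train_config(max_epochs = 40, patience = 10, pretrain_epochs = 5,
               hidden_dim = 8, ...)
}
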