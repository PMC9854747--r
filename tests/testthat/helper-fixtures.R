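# Shared fixtures, memoized across test files so expensive artifacts (trained
# autoencoders, full pipeline fits) are computed once per test run.
#
# Scales used in the tests: pipeline fits run the identical layer stack on
# 32 x 32 spectrograms with short autoencoder training; the dedicated
# reconstruction-error separation checks use 64 x 64 images. The vignette
# documents these sizes as the package's desk-scale choices.

fixture_env <- new.env(parent = emptyenv())

fixture <- function(key, expr) {
  if (!exists(key, envir = fixture_env)) {
    assign(key, force(expr), envir = fixture_env)
  }
  get(key, envir = fixture_env)
}

pipeline_seeds <- 1:5

# Full study-scale pipeline fit: 271 segments per class, desk-scale images.
fx_pipeline <- function(seed) {
  fixture(paste0("pipeline_", seed), {
    ds <- generate_quality_dataset(271, seed = seed)
    model <- fit_sqa_pipeline(ds, image_size = 32, ae_epochs = 4,
                              ae_learning_rate = 3e-3,
                              ae_train_size = 96, seed = seed)
    list(dataset = ds, model = model)
  })
}

# Autoencoder separation fixture: train on 100 high-quality spectrograms at
# 64 x 64, hold out 40 high- and 40 low-quality segments.
fx_ae_separation <- function(seed) {
  fixture(paste0("ae_sep_", seed), {
    ds <- generate_quality_dataset(c(HIGH = 140, MEDIUM = 1, LOW = 40),
                                   seed = seed + 100)
    sps <- lapply(ds$segments, make_spectrogram, size = 64)
    hi <- which(ds$labels == "HIGH")
    lo <- which(ds$labels == "LOW")
    ae <- build_ae(ae_architecture(image_size = 64), seed = seed)
    ae <- train_ae(ae, sps[hi[1:100]], epochs = 6, batch_size = 64,
                   learning_rate = 3e-3, seed = seed)
    list(
      mse_high = ae_mse_batch(ae, sps[hi[101:140]]),
      mse_low = ae_mse_batch(ae, sps[lo])
    )
  })
}

# Small labeled dataset (short recordings) for cheap unit tests.
fx_small_dataset <- function() {
  fixture("small_dataset", {
    generate_quality_dataset(4, seed = 42, duration = 12)
  })
}

# Tiny trained autoencoder (32 x 32) for feature-extraction tests.
fx_tiny_ae <- function() {
  fixture("tiny_ae", {
    ds <- fx_small_dataset()
    sps <- lapply(ds$segments[ds$labels == "HIGH"], make_spectrogram,
                  size = 32)
    ae <- build_ae(ae_architecture(image_size = 32), seed = 5)
    train_ae(ae, sps, epochs = 2, batch_size = 4, seed = 5)
  })
}

# Well-separated 3-cluster matrix: 2 informative + 10 noise features.
make_cluster_matrix <- function(seed, n_per_cluster = 60, separation = 8,
                                cluster_sd = 0.5, n_noise = 10) {
  set.seed(seed)
  centers <- matrix(c(0, 0, separation, 0, 0, separation), ncol = 2,
                    byrow = TRUE)
  cl <- rep(1:3, each = n_per_cluster)
  X <- cbind(
    centers[cl, 1] + rnorm(3 * n_per_cluster, 0, cluster_sd),
    centers[cl, 2] + rnorm(3 * n_per_cluster, 0, cluster_sd),
    matrix(rnorm(3 * n_per_cluster * n_noise), ncol = n_noise)
  )
  colnames(X) <- c("inf1", "inf2", paste0("noise", seq_len(n_noise)))
  list(X = X, clusters = cl)
}
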