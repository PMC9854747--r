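# Spectrogram autoencoder: a fully convolutional encoder/decoder trained on
# high-quality spectrograms only. Because the network never sees noisy
# spectrograms during training, its reconstruction error (AE_MSE) grows as
# segment quality degrades, which is what makes it usable as a quality
# feature.

ae_filters <- c(64, 32, 32, 32, 64, 1, 1, 64, 32, 32, 32, 64, 1)
ae_strides <- c(2, 2, 2, 2, 2, 1, 1, 2, 2, 2, 2, 2, 1)

#' Autoencoder architecture description
#'
#' Thirteen 3x3 conv/deconv layers: six encoder FCN layers (conv + batch
#' norm + ELU), six decoder FCN layers (deconv + batch norm + ELU) and a
#' stride-1 sigmoid output convolution. Filters are
#' 64, 32, 32, 32, 64, 1, 1, 64, 32, 32, 32, 64, 1 with strides
#' 2, 2, 2, 2, 2, 1, 1, 2, 2, 2, 2, 2, 1. The output layer's filter count is
#' the image channel count (3), so input and output are both
#' `image_size x image_size x 3`.
#'
#' @param image_size input image side length in pixels; must be divisible by
#'   32 (five stride-2 stages). 128 is the reference size; 64 or 32 give a
#'   cheaper model for quick experiments with the identical layer stack.
#' @param channels image channel count.
#' @param filters,strides layer specification; overriding the defaults is
#'   validated against the structural invariants.
#' @return object of class `fecg_ae_architecture`.
#' @export
ae_architecture <- function(image_size = 128, channels = 3,
                            filters = ae_filters, strides = ae_strides) {
  if (length(filters) != 13 || length(strides) != 13) {
    stopf("architecture must have 13 layers (got %d filters, %d strides)",
          length(filters), length(strides))
  }
  if (image_size %% 32 != 0 || image_size < 32) {
    stopf("'image_size' must be a positive multiple of 32")
  }
  structure(list(
    image_size = as.integer(image_size),
    channels = as.integer(channels),
    filters = as.integer(filters),
    strides = as.integer(strides),
    kernel = 3L,
    types = c(rep("conv", 6), rep("deconv", 6), "conv")
  ), class = "fecg_ae_architecture")
}

#' Build an (untrained) spectrogram autoencoder
#'
#' Initializes all layer weights (He-scaled Gaussian), batch-normalization
#' parameters and running statistics for the layer stack of
#' [ae_architecture()]. Construction validates that consecutive layer shapes
#' chain correctly and names the offending layer otherwise.
#'
#' @param architecture an [ae_architecture()] object.
#' @param seed integer seed for weight initialization.
#' @return object of class `fecg_ae` with `trained = FALSE`.
#' @export
build_ae <- function(architecture = ae_architecture(), seed = 1L) {
  if (!inherits(architecture, "fecg_ae_architecture")) {
    stopf("'architecture' must come from ae_architecture()")
  }
  arch <- architecture
  n_layers <- length(arch$filters)
  in_ch <- arch$channels
  layers <- vector("list", n_layers)
  with_seed(seed, {
    for (l in seq_len(n_layers)) {
      out_ch <- if (l == n_layers) arch$channels else arch$filters[l]
      if (in_ch < 1 || out_ch < 1) {
        stopf("layer %d: invalid channel chain (%d -> %d)", l, in_ch, out_ch)
      }
      fan_in <- in_ch * arch$kernel^2
      layers[[l]] <- list(
        type = arch$types[l],
        stride = arch$strides[l],
        in_ch = in_ch,
        out_ch = out_ch,
        W = matrix(stats::rnorm(out_ch * fan_in, 0, sqrt(2 / fan_in)),
                   nrow = out_ch),
        b = numeric(out_ch),
        bn = l < n_layers,
        gamma = rep(1, out_ch),
        beta = numeric(out_ch),
        run_mean = numeric(out_ch),
        run_var = rep(1, out_ch),
        activation = if (l == n_layers) "sigmoid" else "elu"
      )
      in_ch <- out_ch
    }
  })
  structure(list(
    layers = layers,
    architecture = arch,
    trained = FALSE,
    loss_trace = NULL,
    training_metadata = NULL,
    seed = as.integer(seed)
  ), class = "fecg_ae")
}

check_image <- function(model, pixels) {
  sz <- model$architecture$image_size
  ch <- model$architecture$channels
  d <- dim(pixels)
  if (length(d) != 3 || d[1] != sz || d[2] != sz || d[3] != ch) {
    stopf("image dimensions %s do not match the model input %dx%dx%d",
          paste(d, collapse = "x"), sz, sz, ch)
  }
  invisible(pixels)
}

as_pixel_list <- function(spectrograms) {
  lapply(spectrograms, function(s) {
    if (inherits(s, "fecg_spectrogram")) s$pixels else s
  })
}

#' Train the autoencoder on high-quality spectrograms
#'
#' Minimizes the mean squared reconstruction error with Adam. The training
#' pool is meant to contain high-quality spectrograms only; widening the gap
#' between high- and low-quality reconstruction errors is the entire point of
#' the feature, so the caller is responsible for the selection (the pipeline
#' wrapper does it from the annotated sample). Batch-normalization inference
#' statistics are set to the average batch statistics of the final epoch.
#'
#' @param model an untrained (or previously trained) `fecg_ae`.
#' @param spectrograms list of `fecg_spectrogram` objects or pixel arrays.
#' @param epochs training epochs.
#' @param batch_size minibatch size (also the batch-normalization batch).
#' @param learning_rate Adam step size.
#' @param seed integer seed for shuffling; together with the build seed this
#'   makes training deterministic.
#' @return the trained `fecg_ae` with a per-epoch `loss_trace`.
#' @export
train_ae <- function(model, spectrograms, epochs = 50, batch_size = 64,
                     learning_rate = 1e-3, seed = 1L) {
  if (!inherits(model, "fecg_ae")) stopf("'model' must come from build_ae()")
  if (length(spectrograms) == 0) stopf("empty training set")
  images <- as_pixel_list(spectrograms)
  for (img in images) check_image(model, img)
  res <- ae_train_cpp(model$layers, images, as.integer(epochs),
                      as.integer(batch_size), learning_rate,
                      as.integer(seed))
  model$layers <- res$layers
  model$trained <- TRUE
  model$loss_trace <- as.numeric(res$loss_trace)
  model$training_metadata <- list(
    epochs = as.integer(epochs), batch_size = as.integer(batch_size),
    learning_rate = learning_rate, seed = as.integer(seed),
    n_images = length(images)
  )
  model
}

#' Reconstruct spectrogram images
#'
#' Runs the autoencoder in inference mode (batch normalization uses running
#' statistics). The sigmoid output keeps every pixel in [0, 1].
#'
#' @param model a trained `fecg_ae`.
#' @param spectrograms one `fecg_spectrogram`/pixel array, or a list of them.
#' @return a pixel array, or a list of pixel arrays for list input.
#' @export
reconstruct <- function(model, spectrograms) {
  if (!inherits(model, "fecg_ae")) stopf("'model' must come from build_ae()")
  single <- inherits(spectrograms, "fecg_spectrogram") ||
    (is.array(spectrograms) && length(dim(spectrograms)) == 3)
  images <- as_pixel_list(if (single) list(spectrograms) else spectrograms)
  for (img in images) check_image(model, img)
  out <- ae_reconstruct_cpp(model$layers, images)
  if (single) out[[1]] else out
}

#' Mean squared reconstruction error between two images
#'
#' The per-pixel mean of squared differences, i.e. the summed squared error
#' divided by `L * M * N` for an `L x M` image with `N` channels.
#'
#' @param s input image (array, or `fecg_spectrogram`).
#' @param s_hat reconstructed image of identical dimensions.
#' @return non-negative mean squared error; 0 iff the reconstruction is
#'   perfect.
#' @export
reconstruction_mse <- function(s, s_hat) {
  a <- if (inherits(s, "fecg_spectrogram")) s$pixels else s
  b <- if (inherits(s_hat, "fecg_spectrogram")) s_hat$pixels else s_hat
  if (!identical(dim(a), dim(b))) stopf("image dimensions differ")
  mean((a - b)^2)
}

#' Autoencoder reconstruction-error feature (AE_MSE)
#'
#' Reconstructs the spectrogram with the trained autoencoder and returns the
#' mean squared reconstruction error. Larger values indicate lower signal
#' quality.
#'
#' @param model a trained `fecg_ae`.
#' @param s one `fecg_spectrogram` or pixel array.
#' @return non-negative AE_MSE value.
#' @export
ae_mse <- function(model, s) {
  if (!isTRUE(model$trained)) stopf("autoencoder is untrained; call train_ae()")
  reconstruction_mse(s, reconstruct(model, s))
}

#' AE_MSE for a list of spectrograms
#'
#' Batched version of [ae_mse()] (one forward pass per image, single call
#' into the network).
#'
#' @inheritParams ae_mse
#' @param spectrograms list of `fecg_spectrogram` objects or pixel arrays.
#' @return numeric vector of AE_MSE values.
#' @export
ae_mse_batch <- function(model, spectrograms) {
  if (!isTRUE(model$trained)) stopf("autoencoder is untrained; call train_ae()")
  images <- as_pixel_list(spectrograms)
  for (img in images) check_image(model, img)
  recs <- ae_reconstruct_cpp(model$layers, images)
  mapply(reconstruction_mse, images, recs)
}

#' Per-layer spatial output sizes
#'
#' @param model `fecg_ae`.
#' @param input_size input image side length (defaults to the architecture's).
#' @return integer vector of spatial sizes after each layer.
#' @export
ae_layer_sizes <- function(model, input_size = NULL) {
  if (is.null(input_size)) input_size <- model$architecture$image_size
  as.integer(ae_layer_sizes_cpp(model$layers, as.integer(input_size)))
}

#' @exportS3Method base::print
print.fecg_ae <- function(x, ...) {
  cat(sprintf("<fecg_ae> %dx%dx%d, 13 layers, %s\n",
              x$architecture$image_size, x$architecture$image_size,
              x$architecture$channels,
              if (isTRUE(x$trained)) {
                sprintf("trained (final loss %.5f)", utils::tail(x$loss_trace, 1))
              } else "untrained"))
  invisible(x)
}
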