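# End-to-end pipeline: spectrograms -> AE (trained on high-quality only) ->
# 12 features -> MCFS top-k -> balanced SOM classifier.

#' Fit the full quality-assessment pipeline
#'
#' Runs every stage on an annotated segment set: renders spectrogram images,
#' trains the autoencoder on the high-quality spectrograms, extracts the
#' twelve features, ranks them with MCFS and keeps the top `n_select`,
#' balances the classes by undersampling, trains the SOM on the selected
#' features and labels its neurons from three sampled segments each.
#'
#' @param dataset `fecg_quality_dataset`, or a list with elements `segments`
#'   and `labels`.
#' @param image_size spectrogram/autoencoder image side (pixels). 128 is the
#'   reference size; 64 runs the identical layer stack at a quarter of the
#'   cost.
#' @param ae_epochs,ae_batch_size,ae_learning_rate autoencoder training
#'   parameters.
#' @param ae_train_size number of high-quality spectrograms used for AE
#'   training (`NULL` = all of them).
#' @param n_select number of MCFS-selected features fed to the SOM.
#' @param grid,som_iterations,som_learning_rate SOM parameters.
#' @param params entropy parameters, see [entropy_params()].
#' @param seed integer seed driving every random stage.
#' @return object of class `fecg_sqa_model`: list with the trained `ae`,
#'   `mcfs` result, `selected` feature names, labeled `som`, the training
#'   `features` matrix and `labels`, and the configuration.
#' @export
fit_sqa_pipeline <- function(dataset,
                             image_size = 128,
                             ae_epochs = 30,
                             ae_batch_size = 64,
                             ae_learning_rate = 1e-3,
                             ae_train_size = NULL,
                             n_select = 5,
                             grid = c(8, 8),
                             som_iterations = 100000,
                             som_learning_rate = 0.5,
                             params = entropy_params(),
                             seed = 1L) {
  segments <- dataset$segments
  labels <- quality_levels(dataset$labels)
  if (length(segments) != length(labels)) {
    stopf("'segments' and 'labels' lengths differ")
  }

  spectrograms <- lapply(segments, make_spectrogram, size = image_size)

  high_idx <- which(labels == "HIGH")
  if (length(high_idx) == 0) stopf("no HIGH-quality segments to train the AE")
  if (!is.null(ae_train_size) && ae_train_size < length(high_idx)) {
    high_idx <- with_seed(seed, sort(sample(high_idx, ae_train_size)))
  }
  ae <- build_ae(ae_architecture(image_size = image_size), seed = seed)
  ae <- train_ae(ae, spectrograms[high_idx], epochs = ae_epochs,
                 batch_size = ae_batch_size,
                 learning_rate = ae_learning_rate, seed = seed)

  X <- extract_feature_matrix(segments, spectrograms, ae, params)

  mcfs <- mcfs_scores(X, n_clusters = 3, n_neighbors = 5)
  selected <- select_top(mcfs, n_select)

  balanced <- balance_dataset(X[, selected, drop = FALSE], labels,
                              seed = seed)
  som <- train_som(balanced$X, grid = grid,
                   learning_rate = som_learning_rate,
                   iterations = som_iterations, seed = seed)
  som <- label_neurons(som, balanced$X, balanced$labels, seed = seed)

  structure(list(
    ae = ae,
    mcfs = mcfs,
    selected = selected,
    som = som,
    features = X,
    labels = labels,
    params = params,
    image_size = image_size,
    seed = as.integer(seed)
  ), class = "fecg_sqa_model")
}

#' Classify segments with a fitted pipeline
#'
#' @param object fitted `fecg_sqa_model`.
#' @param segments list of `fecg_segment` objects (pre-processed like the
#'   training data), or a precomputed feature matrix containing at least the
#'   selected feature columns.
#' @param ... unused.
#' @return quality factor, one level per segment.
#' @export
predict.fecg_sqa_model <- function(object, segments, ...) {
  X <- if (is.matrix(segments)) {
    segments
  } else {
    extract_feature_matrix(segments, ae = object$ae, params = object$params,
                           image_size = object$image_size)
  }
  classify(object$som, X[, object$selected, drop = FALSE])
}

#' Evaluate a fitted pipeline on labeled segments
#'
#' Convenience wrapper: predicts quality levels (on the training set itself
#' by default, the protocol used with unsupervised clustering classifiers)
#' and computes the classification report.
#'
#' @param model fitted `fecg_sqa_model`.
#' @param dataset optional `fecg_quality_dataset`; defaults to the training
#'   features stored in the model.
#' @return `fecg_classification_report`.
#' @export
evaluate_sqa_model <- function(model, dataset = NULL) {
  if (is.null(dataset)) {
    pred <- classify(model$som,
                     model$features[, model$selected, drop = FALSE])
    return(classification_report(model$labels, pred))
  }
  pred <- predict(model, dataset$segments)
  classification_report(dataset$labels, pred)
}

#' @exportS3Method base::print
print.fecg_sqa_model <- function(x, ...) {
  cat(sprintf("<fecg_sqa_model> %d training segments, image size %d\n",
              nrow(x$features), x$image_size))
  cat("  selected features:", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}
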