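# Self-organizing-map three-level classifier. The SOM is trained online with
# a bubble neighborhood; neurons are then labeled from at most three sampled
# winner segments each, so only a handful of annotations is needed, and every
# new segment inherits the label of its winning neuron.

#' Undersample to equal class counts
#'
#' Randomly undersamples every majority class to the minority-class count.
#' Classes already at the minimum keep all their rows; kept rows stay in
#' their original order.
#'
#' @param X feature matrix (rows = segments).
#' @param labels class labels, one per row.
#' @param seed integer seed for the undersampling draw.
#' @return object of class `fecg_balanced`: list with `X`, `labels`,
#'   `kept_indices` and `seed`.
#' @export
balance_dataset <- function(X, labels, seed = 1L) {
  X <- as.matrix(X)
  labels <- quality_levels(labels)
  if (nrow(X) != length(labels)) stopf("'X' and 'labels' lengths differ")
  counts <- table(labels)
  if (any(counts == 0)) {
    stopf("class(es) absent from 'labels': %s",
          paste(names(counts)[counts == 0], collapse = ", "))
  }
  m <- min(counts)
  kept <- with_seed(seed, {
    unlist(lapply(levels(labels), function(cl) {
      idx <- which(labels == cl)
      if (length(idx) > m) sort(sample(idx, m)) else idx
    }))
  })
  kept <- sort(kept)
  structure(list(
    X = X[kept, , drop = FALSE],
    labels = labels[kept],
    kept_indices = kept,
    seed = as.integer(seed)
  ), class = "fecg_balanced")
}

# Row-major lexicographic neuron coordinates: neuron k <-> (row, col) with
# the column varying fastest, so index order == lexicographic (row, col).
som_coords <- function(grid) {
  cbind(row = rep(seq_len(grid[1]), each = grid[2]),
        col = rep(seq_len(grid[2]), times = grid[1]))
}

#' Construct a SOM model from explicit weights
#'
#' Low-level constructor, mainly useful for programmatic models in tests and
#' for deserialization; [train_som()] is the normal entry point.
#'
#' @param weights numeric matrix (`prod(grid)` x d), one weight vector per
#'   neuron in row-major grid order.
#' @param grid `c(rows, cols)` lattice dimensions.
#' @param center,scale standardization statistics applied to inputs before
#'   distance computation (defaults: no scaling).
#' @return object of class `fecg_som`.
#' @export
som_model <- function(weights, grid, center = NULL, scale = NULL) {
  weights <- as.matrix(weights)
  grid <- as.integer(grid)
  if (nrow(weights) != prod(grid)) {
    stopf("'weights' must have prod(grid) = %d rows", prod(grid))
  }
  d <- ncol(weights)
  structure(list(
    weights = weights,
    grid = grid,
    coords = som_coords(grid),
    center = if (is.null(center)) numeric(d) else center,
    scale = if (is.null(scale)) rep(1, d) else scale,
    neuron_labels = NULL,
    feature_names = colnames(weights)
  ), class = "fecg_som")
}

som_standardize <- function(model, X) {
  X <- if (is.matrix(X)) X else matrix(X, nrow = 1)
  if (ncol(X) != ncol(model$weights)) {
    stopf("input dimension %d does not match the SOM weight dimension %d",
          ncol(X), ncol(model$weights))
  }
  sweep(sweep(X, 2, model$center, "-"), 2, model$scale, "/")
}

# n x K squared-distance matrix between standardized rows and neuron
# weights. Computed per neuron as rowSums((X - w)^2): marginally slower than
# the expanded quadratic form but free of its cancellation error, so exact
# matches give exactly zero.
som_dist2 <- function(model, Xs) {
  W <- model$weights
  d2 <- matrix(0, nrow(Xs), nrow(W))
  for (k in seq_len(nrow(W))) {
    d2[, k] <- rowSums(sweep(Xs, 2, W[k, ], "-")^2)
  }
  d2
}

#' Train a self-organizing map
#'
#' Online SOM training: features are standardized (statistics stored in the
#' model), weights are initialized uniformly within the per-dimension data
#' range, and for each of `iterations` steps one sample is drawn uniformly
#' with replacement, its winning neuron found by minimal Euclidean distance,
#' and the winner plus all neurons within the current bubble radius receive
#' the full update `lr(t) * (x - w)`. The learning rate decays as
#' `lr0 / (1 + t / (T/2))` and the bubble radius linearly from half the grid
#' to 1.
#'
#' @param X numeric feature matrix (rows = samples); must be finite.
#' @param grid `c(rows, cols)` lattice size.
#' @param learning_rate initial learning rate.
#' @param iterations number of online updates.
#' @param neighborhood neighborhood function; only `"bubble"` is supported.
#' @param radius initial bubble radius (default: half the larger grid side).
#' @param seed integer seed (weight initialization and sample draws).
#' @return trained `fecg_som` with quantization-error bookkeeping
#'   (`qe_initial`, `qe_final`).
#' @export
train_som <- function(X, grid = c(8, 8), learning_rate = 0.5,
                      iterations = 100000, neighborhood = "bubble",
                      radius = NULL, seed = 1L) {
  X <- as.matrix(X)
  if (nrow(X) == 0) stopf("'X' is empty")
  if (any(!is.finite(X))) stopf("'X' contains non-finite values")
  if (neighborhood != "bubble") {
    stopf("only the 'bubble' neighborhood is implemented")
  }
  if (is.null(radius)) radius <- max(grid) / 2

  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd)
  scale[scale == 0] <- 1
  Xs <- sweep(sweep(X, 2, center, "-"), 2, scale, "/")

  K <- prod(grid)
  d <- ncol(X)
  rng <- apply(Xs, 2, range)
  W0 <- with_seed(seed, {
    matrix(stats::runif(K * d, rep(rng[1, ], each = K),
                        rep(rng[2, ], each = K)), nrow = K)
  })
  model <- som_model(W0, grid, center, scale)
  model$feature_names <- colnames(X)
  qe0 <- quantization_error(model, X)

  coords <- som_coords(grid)
  Wt <- som_train_cpp(Xs, W0, coords, learning_rate, as.integer(iterations),
                      radius, as.integer(seed))
  model$weights <- Wt
  model$seed <- as.integer(seed)
  model$iterations <- as.integer(iterations)
  model$learning_rate <- learning_rate
  model$neighborhood <- neighborhood
  model$radius <- radius
  model$qe_initial <- qe0
  model$qe_final <- quantization_error(model, X)
  model
}

#' Winning neuron of a feature vector
#'
#' Standardizes the input with the model's training statistics and returns
#' the neuron with minimal Euclidean distance; exact ties go to the
#' lexicographically smallest (row, column).
#'
#' @param model `fecg_som`.
#' @param x feature vector (length = weight dimension) or matrix of rows.
#' @return for a single vector, a list with `index`, `row`, `col`,
#'   `distance`; for a matrix, an integer vector of neuron indices.
#' @export
winning_neuron <- function(model, x) {
  single <- !is.matrix(x)
  Xs <- som_standardize(model, x)
  d2 <- som_dist2(model, Xs)
  win <- max.col(-d2, ties.method = "first")
  if (!single) return(win)
  list(index = win[1],
       row = model$coords[win[1], 1],
       col = model$coords[win[1], 2],
       distance = sqrt(max(0, d2[1, win[1]])))
}

#' Quantization error
#'
#' Mean Euclidean distance (in the standardized feature space) from each row
#' to its winning neuron's weight vector.
#'
#' @param model `fecg_som`.
#' @param X feature matrix.
#' @return non-negative mean distance.
#' @export
quantization_error <- function(model, X) {
  X <- if (is.matrix(X)) X else matrix(X, nrow = 1)
  if (nrow(X) == 0) stopf("'X' is empty")
  Xs <- som_standardize(model, X)
  d2 <- som_dist2(model, Xs)
  mean(sqrt(pmax(0, apply(d2, 1, min))))
}

# Majority label with ties resolved toward the lowest quality present,
# i.e. the most conservative choice for downstream removal.
majority_label <- function(lbls) {
  counts <- table(lbls)
  top <- names(counts)[counts == max(counts)]
  top[length(top)]  # levels ordered HIGH > MEDIUM > LOW; last tied = lowest
}

#' Label SOM neurons from a few annotated segments
#'
#' For every neuron, collects the training rows it wins; if three or more,
#' samples three without replacement and takes the majority label (ties
#' resolved toward LOW); with one or two winners, the majority of all of
#' them; neurons that win nothing inherit the label of the nearest labeled
#' neuron on the grid (ties lexicographic). Only the sampled rows' labels are
#' ever read, which is why a large unlabeled dataset plus a few annotations
#' suffices.
#'
#' @param model trained `fecg_som`.
#' @param X training feature matrix.
#' @param labels quality labels aligned with the rows of `X`.
#' @param samples_per_neuron annotated samples drawn per neuron.
#' @param seed integer seed for the per-neuron draws.
#' @return the model with `neuron_labels` set (quality factor, one per
#'   neuron).
#' @export
label_neurons <- function(model, X, labels, samples_per_neuron = 3,
                          seed = 1L) {
  X <- as.matrix(X)
  labels <- quality_levels(labels)
  win <- winning_neuron(model, X)
  K <- nrow(model$weights)
  if (length(unique(win)) == 0) stopf("no neuron wins any training sample")
  neuron_labels <- rep(NA_character_, K)
  with_seed(seed, {
    for (k in seq_len(K)) {
      members <- which(win == k)
      if (length(members) == 0) next
      picked <- if (length(members) > samples_per_neuron) {
        sample(members, samples_per_neuron)
      } else {
        members
      }
      if (any(is.na(labels[picked]))) {
        stopf("missing label for a sampled segment (neuron %d)", k)
      }
      neuron_labels[k] <- majority_label(labels[picked])
    }
  })
  if (all(is.na(neuron_labels))) stopf("no neuron wins any training sample")
  # complete empty neurons from the nearest labeled neuron on the grid
  unlabeled <- which(is.na(neuron_labels))
  labeled <- which(!is.na(neuron_labels))
  for (k in unlabeled) {
    dg <- rowSums((model$coords[labeled, , drop = FALSE] -
                     matrix(model$coords[k, ], length(labeled), 2,
                            byrow = TRUE))^2)
    neuron_labels[k] <- neuron_labels[labeled[which.min(dg)]]
  }
  model$neuron_labels <- quality_levels(neuron_labels)
  model
}

#' Classify feature vectors with a labeled SOM
#'
#' @param model labeled `fecg_som` (after [label_neurons()]).
#' @param x feature vector or matrix of rows.
#' @return quality factor, one level per input row.
#' @export
classify <- function(model, x) {
  if (is.null(model$neuron_labels)) {
    stopf("model has no neuron labels; call label_neurons() first")
  }
  win <- if (is.matrix(x)) winning_neuron(model, x) else
    winning_neuron(model, x)$index
  lab <- model$neuron_labels[win]
  if (any(is.na(lab))) stopf("classification hit an unlabeled neuron")
  lab
}

#' @exportS3Method base::print
print.fecg_som <- function(x, ...) {
  cat(sprintf("<fecg_som> %dx%d grid, %d-dimensional, %s\n",
              x$grid[1], x$grid[2], ncol(x$weights),
              if (is.null(x$neuron_labels)) "unlabeled" else "labeled"))
  if (!is.null(x$qe_final)) {
    cat(sprintf("  quantization error: %.4f (init %.4f)\n",
                x$qe_final, x$qe_initial))
  }
  invisible(x)
}
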