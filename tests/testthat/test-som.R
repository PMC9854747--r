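make_test_som <- function(seed = 1, grid = c(3, 3), d = 4) {
  set.seed(seed)
  som_model(matrix(rnorm(prod(grid) * d), nrow = prod(grid)), grid)
}

test_that("balance_dataset undersamples to the minority count", {
  set.seed(1)
  labels <- c(rep("MEDIUM", 500), rep("HIGH", 300), rep("LOW", 271))
  X <- matrix(rnorm(length(labels) * 3), ncol = 3)
  b <- balance_dataset(X, labels, seed = 7)
  expect_equal(as.numeric(table(b$labels)), c(271, 271, 271))
  expect_equal(nrow(b$X), 813)
  b2 <- balance_dataset(X, labels, seed = 7)
  expect_identical(b$kept_indices, b2$kept_indices)

  labs_eq <- rep(c("HIGH", "MEDIUM", "LOW"), each = 10)
  Xeq <- matrix(rnorm(90), ncol = 3)
  beq <- balance_dataset(Xeq, labs_eq, seed = 1)
  expect_identical(beq$kept_indices, 1:30)
  expect_identical(beq$X, Xeq)

  expect_error(balance_dataset(Xeq, rep(c("HIGH", "MEDIUM"), 15), seed = 1),
               "absent")
})

test_that("winning neuron equals the exhaustive scan and breaks ties lexicographically", {
  model <- make_test_som(2)
  set.seed(3)
  for (i in 1:100) {
    x <- rnorm(4)
    expect_identical(winning_neuron(model, x)$index, oracle_winner(model, x))
  }
  # exact tie: two identical neurons -> smallest (row, col) wins
  W <- matrix(1, 4, 2)
  W[3, ] <- c(5, 5)
  W[4, ] <- c(7, 7)
  tie_model <- som_model(W, c(2, 2))
  win <- winning_neuron(tie_model, c(1, 1))
  expect_equal(win$index, 1)
  expect_equal(unname(c(win$row, win$col)), c(1, 1))
  expect_equal(win$distance, 0)

  one <- som_model(matrix(c(0, 0), 1), c(1, 1))
  expect_equal(winning_neuron(one, c(9, 9))$index, 1)

  expect_error(winning_neuron(model, c(1, 2)), "dimension")
})

test_that("quantization error matches its brute-force recomputation", {
  model <- make_test_som(4)
  expect_equal(quantization_error(model, model$weights), 0, tolerance = 1e-12)
  x <- model$weights[5, ] + c(2, 0, 0, 0)
  expect_equal(quantization_error(model, matrix(x, 1)), 2, tolerance = 1e-9)
  set.seed(5)
  X <- matrix(rnorm(40), ncol = 4)
  expect_equal(quantization_error(model, X),
               oracle_quantization_error(model, X), tolerance = 1e-9)
  expect_error(quantization_error(model, X[0, , drop = FALSE]), "empty")
})

test_that("training reduces quantization error and is deterministic", {
  set.seed(6)
  X <- rbind(matrix(rnorm(100, 0), ncol = 2),
             matrix(rnorm(100, 5), ncol = 2))
  for (seed in 1:5) {
    som <- train_som(X, grid = c(4, 4), iterations = 2000, seed = seed)
    expect_lte(som$qe_final, som$qe_initial)
  }
  s1 <- train_som(X, grid = c(4, 4), iterations = 2000, seed = 9)
  s2 <- train_som(X, grid = c(4, 4), iterations = 2000, seed = 9)
  expect_identical(s1$weights, s2$weights)
  Xbad <- X
  Xbad[3, 1] <- NaN
  expect_error(train_som(Xbad, iterations = 10), "non-finite")
  expect_error(train_som(X, neighborhood = "gaussian"), "bubble")
})

test_that("three separated Gaussian clusters are recovered almost perfectly", {
  for (seed in c(1, 2)) {
    set.seed(seed)
    n <- 100
    mu <- matrix(rnorm(15, sd = 4), 3)
    X <- do.call(rbind, lapply(1:3, function(k) {
      matrix(rnorm(n * 5, mean = rep(mu[k, ], each = n), sd = 0.5), ncol = 5)
    }))
    labels <- quality_levels(rep(c("HIGH", "MEDIUM", "LOW"), each = n))
    som <- train_som(X, iterations = 20000, seed = seed)
    som <- label_neurons(som, X, labels, seed = seed)
    pred <- classify(som, X)
    expect_gte(mean(pred == labels), 0.95)
    rep <- classification_report(labels, pred)
    expect_gte(min(rep$per_class$recall), 0.9)
  }
})

test_that("neuron labeling follows majority, completion and tie rules", {
  # 1x2 grid, 1-D weights at 0 and 10; winners are unambiguous
  model <- som_model(matrix(c(0, 10), ncol = 1), c(1, 2))
  X <- matrix(c(0.1, -0.1, 0.2, 9.9), ncol = 1)
  labels <- c("LOW", "LOW", "HIGH", "MEDIUM")
  m <- label_neurons(model, X, labels, seed = 1)
  expect_equal(as.character(m$neuron_labels[1]), "LOW")    # majority of 3
  expect_equal(as.character(m$neuron_labels[2]), "MEDIUM") # single winner

  # three-way tie resolves toward LOW
  m2 <- label_neurons(model, matrix(c(0.1, -0.1, 0.2, 9.9), ncol = 1),
                      c("HIGH", "MEDIUM", "LOW", "HIGH"), seed = 1)
  expect_equal(as.character(m2$neuron_labels[1]), "LOW")

  # empty neurons inherit the nearest labeled neuron on the grid
  model3 <- som_model(matrix(c(0, 10, 20), ncol = 1), c(1, 3))
  m3 <- label_neurons(model3, matrix(c(0.1, 0.2, -0.1), ncol = 1),
                      c("HIGH", "HIGH", "HIGH"), seed = 1)
  expect_true(all(as.character(m3$neuron_labels) == "HIGH"))

  # scripted replay: sampling three of many winners follows the seeded draw
  model4 <- som_model(matrix(0, ncol = 1, nrow = 1), c(1, 1))
  Xm <- matrix(rnorm(10, 0, 0.1), ncol = 1)
  labs <- c(rep("HIGH", 5), rep("LOW", 5))
  m4 <- label_neurons(model4, Xm, labs, seed = 4)
  expected <- fecgsqa:::with_seed(4, {
    picked <- sample(1:10, 3)
    counts <- table(quality_levels(labs[picked]))
    top <- names(counts)[counts == max(counts)]
    top[length(top)]
  })
  expect_equal(as.character(m4$neuron_labels[1]), expected)
})

test_that("classification requires labels and is deterministic", {
  model <- make_test_som(8)
  expect_error(classify(model, model$weights[1, ]), "labels")
  model$neuron_labels <- quality_levels(rep(c("HIGH", "MEDIUM", "LOW"),
                                            each = 3))
  expect_equal(as.character(classify(model, model$weights[4, ])), "MEDIUM")
  X <- matrix(rnorm(20 * 4), ncol = 4)
  expect_identical(classify(model, X), classify(model, X))
})
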