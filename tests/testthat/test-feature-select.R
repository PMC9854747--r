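test_that("informative features outrank noise on separated clusters", {
  for (seed in c(1, 2)) {
    cm <- make_cluster_matrix(seed)
    r <- mcfs_scores(cm$X, n_clusters = 3, n_neighbors = 5)
    expect_setequal(r$ranking[1:2], c("inf1", "inf2"))
    expect_true(all(r$scores >= 0))
    # ranking is by descending score with ties broken by column order
    expect_identical(r$ranking, colnames(cm$X)[order(-r$scores)])
  }
})

test_that("scores are invariant to row permutation and column rescaling", {
  cm <- make_cluster_matrix(3)
  r <- mcfs_scores(cm$X, 3, 5)
  set.seed(33)
  rp <- mcfs_scores(cm$X[sample(nrow(cm$X)), ], 3, 5)
  expect_equal(r$scores, rp$scores, tolerance = 1e-8)
  Xa <- cm$X
  Xa[, "inf1"] <- 100 * Xa[, "inf1"] - 7
  ra <- mcfs_scores(Xa, 3, 5)
  expect_equal(r$scores, ra$scores, tolerance = 1e-8)
})

test_that("duplicated columns share their score", {
  cm <- make_cluster_matrix(4)
  X2 <- cbind(cm$X, inf1b = cm$X[, "inf1"])
  r <- mcfs_scores(X2, 3, 5)
  expect_equal(r$scores[["inf1"]], r$scores[["inf1b"]], tolerance = 0.02)
})

test_that("pure-noise matrices produce no spuriously dominant feature", {
  worst <- 0
  for (seed in 1:20) {
    set.seed(seed)
    Xn <- matrix(rnorm(100 * 12), ncol = 12)
    rn <- mcfs_scores(Xn, 3, 5)
    worst <- max(worst, max(rn$scores) / stats::median(rn$scores))
  }
  expect_lt(worst, 3)
})

test_that("select_top returns the leading ranking slice and validates k", {
  cm <- make_cluster_matrix(5)
  r <- mcfs_scores(cm$X, 3, 5)
  expect_length(select_top(r, 5), 5)
  expect_identical(select_top(r, 5), r$ranking[1:5])
  expect_identical(select_top(r, 12), r$ranking)
  expect_error(select_top(r, 0), "between")
  expect_error(select_top(r, 13), "between")
  expect_error(select_top(list(), 5), "mcfs_scores")
})

test_that("non-finite features are rejected", {
  cm <- make_cluster_matrix(6)
  X <- cm$X
  X[1, 1] <- NA
  expect_error(mcfs_scores(X, 3, 5), "non-finite")
})
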