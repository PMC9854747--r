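test_that("template entropies match brute-force counting on short inputs", {
  x <- rep(c(1, 2), 5)
  r_abs <- 0.2 * sd(x)
  expect_equal(approximate_entropy(x, 2, 0.2), oracle_appen(x, 2, r_abs),
               tolerance = 1e-12)
  set.seed(11)
  y <- rnorm(80)
  expect_equal(approximate_entropy(y, 2, 0.2),
               oracle_appen(y, 2, 0.2 * sd(y)), tolerance = 1e-12)
  z <- rep(c(0, 1), 100)
  expect_equal(sample_entropy(z, 2, 0.2),
               oracle_sampen(z, 2, 0.2 * sd(z)), tolerance = 1e-12)
  expect_equal(sample_entropy(y, 2, 0.2),
               oracle_sampen(y, 2, 0.2 * sd(y)), tolerance = 1e-12)
})

test_that("entropy limit cases behave as the definitions require", {
  expect_equal(approximate_entropy(rep(3, 50)), 0)
  expect_equal(sample_entropy(rep(3, 50)), 0)
  expect_error(approximate_entropy(c(1, 2), m = 2), "short")

  # SampEn is invariant to affine rescaling when r is sd-relative
  set.seed(2)
  w <- rnorm(150)
  expect_equal(sample_entropy(w), sample_entropy(5 * w + 3),
               tolerance = 1e-12)

  # irregular noise is more entropic than a slow tone
  set.seed(3)
  noise <- runif(1000)
  tone <- sin(2 * pi * 2 * seq(0, 1, length.out = 1000))
  expect_gt(approximate_entropy(noise), approximate_entropy(tone))
})

test_that("spectral entropy is normalized and orders flat vs tonal spectra", {
  set.seed(4)
  noise <- rnorm(4096)
  expect_gt(spectral_entropy(noise, 1000), 0.9)
  tone <- sin(2 * pi * 50 * seq(0, 4.095, by = 1e-3))
  expect_lt(spectral_entropy(tone, 1000), 0.3)
  for (x in list(noise, tone, cumsum(rnorm(2000)))) {
    v <- spectral_entropy(x, 1000)
    expect_gte(v, 0)
    expect_lte(v, 1)
  }
  expect_error(spectral_entropy(rep(1, 100), 1000), "degenerate")
})

test_that("permutation entropy matches hand enumeration and its limits", {
  # [1,3,2,4,3,5], order 2: patterns up,down,up,down,up -> p = (3/5, 2/5)
  p <- c(3, 2) / 5
  expect_equal(permutation_entropy(c(1, 3, 2, 4, 3, 5), 2, 1),
               -sum(p * log(p)) / log(2), tolerance = 1e-12)
  expect_equal(permutation_entropy(seq_len(200), 3, 1), 0)
  set.seed(5)
  expect_gt(permutation_entropy(runif(10000), 3, 1), 0.99)
  # equals the pattern-table oracle, including ties, for several draws
  for (seed in 1:5) {
    set.seed(seed)
    x <- sample(0:3, 60, replace = TRUE)  # many ties
    expect_equal(permutation_entropy(x, 3, 1), oracle_pen(x, 3, 1),
                 tolerance = 1e-12)
    y <- rnorm(60)
    expect_equal(permutation_entropy(y, 4, 2), oracle_pen(y, 4, 2),
                 tolerance = 1e-12)
  }
  expect_error(permutation_entropy(c(1, 2, 3), order = 5), "short")
})

test_that("DFA recovers the scaling exponents of canonical processes", {
  set.seed(6)
  wn <- rnorm(3000)
  a_wn <- dfa_alpha(wn)
  expect_gte(a_wn, 0.4)
  expect_lte(a_wn, 0.6)
  rw <- cumsum(rnorm(3000))
  a_rw <- dfa_alpha(rw)
  expect_gte(a_rw, 1.35)
  expect_lte(a_rw, 1.65)
  expect_equal(dfa_alpha(7 * wn), a_wn, tolerance = 1e-9)
  expect_error(dfa_alpha(rnorm(32)), "short")
})

test_that("fractal dimensions hit their analytic anchors", {
  line <- seq(0, 1, length.out = 500)
  expect_equal(katz_fd(line), 1, tolerance = 1e-6)
  expect_equal(katz_fd(rep(2, 100)), 1)
  h_line <- higuchi_fd(line, kmax = 10)
  expect_gte(h_line, 1)
  expect_lte(h_line, 1.05)
  set.seed(7)
  wn <- rnorm(3000)
  h_wn <- higuchi_fd(wn, kmax = 10)
  expect_gte(h_wn, 1.9)
  expect_lte(h_wn, 2.05)
  expect_gt(katz_fd(wn[1:500]), katz_fd(sin(2 * pi * 5 * line)))
  # oracle equivalence on short inputs
  for (seed in 1:5) {
    set.seed(seed)
    x <- rnorm(100)
    expect_equal(higuchi_fd(x, 8), oracle_higuchi(x, 8), tolerance = 1e-9)
  }
})

test_that("moment SQIs match theory and are affine invariant", {
  set.seed(8)
  g <- rnorm(100000)
  m <- moment_sqis(g)
  expect_gte(m[["kSQI"]], 2.9)
  expect_lte(m[["kSQI"]], 3.1)
  expect_gte(m[["sSQI"]], -0.05)
  expect_lte(m[["sSQI"]], 0.05)

  two_point <- rep(c(-1, 1), 50)
  m2 <- moment_sqis(two_point)
  expect_equal(m2[["kSQI"]], 1)
  expect_equal(m2[["sSQI"]], 0)

  x <- rnorm(500)
  expect_equal(moment_sqis(x), moment_sqis(3 * x + 10), tolerance = 1e-9)
  expect_error(moment_sqis(rep(1, 10)), "degenerate")
})

test_that("spectral quality indices respect their band definitions", {
  fs <- 1000
  t <- seq(0, 3, by = 1 / fs)
  expect_gte(psqi(sin(2 * pi * 10 * t), fs), 0.95)
  expect_lte(psqi(sin(2 * pi * 30 * t), fs), 0.05)
  expect_gte(bassqi(sin(2 * pi * 10 * t), fs), 0.95)
  expect_lte(bassqi(sin(2 * pi * 0.5 * t), fs), 0.1)
  set.seed(9)
  for (x in list(rnorm(3000), cumsum(rnorm(3000)))) {
    expect_gte(psqi(x, fs), 0)
    expect_lte(psqi(x, fs), 1)
    expect_gte(bassqi(x, fs), 0)
    expect_lte(bassqi(x, fs), 1)
  }
})

test_that("extract_features returns the 12 named finite features in order", {
  ds <- fx_small_dataset()
  ae <- fx_tiny_ae()
  seg <- ds$segments[[1]]
  sp <- make_spectrogram(seg, size = 32)
  fv <- extract_features(seg, sp, ae)
  expect_identical(names(fv), feature_names())
  expect_length(fv, 12)
  expect_true(all(is.finite(fv)))
  expect_identical(names(extract_features(ds$segments[[5]],
                                          make_spectrogram(ds$segments[[5]],
                                                           size = 32),
                                          ae)),
                   feature_names())
})

test_that("feature matrix rows align with segments and stay finite", {
  ds <- fx_small_dataset()
  ae <- fx_tiny_ae()
  X <- extract_feature_matrix(ds$segments[1:4], ae = ae, image_size = 32)
  expect_equal(dim(X), c(4, 12))
  expect_true(all(is.finite(X)))
  expect_identical(colnames(X), feature_names())
})

test_that("feature errors are tagged with the failing feature name", {
  ds <- fx_small_dataset()
  ae <- fx_tiny_ae()
  const_seg <- structure(list(samples = rep(1, 3000),
                              sampling_frequency = 1000, start_time = 0,
                              label = NULL, id = "const"),
                         class = "fecg_segment")
  sp <- make_spectrogram(const_seg, size = 32)
  expect_error(extract_features(const_seg, sp, ae), "feature SpecEn")
  expect_error(psqi(rnorm(100), fs = 50), "80")
})
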