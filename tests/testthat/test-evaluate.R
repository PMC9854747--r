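test_that("perfect predictions give unit metrics and a diagonal confusion", {
  labs <- rep(c("HIGH", "MEDIUM", "LOW"), times = c(5, 7, 3))
  r <- classification_report(labs, labs)
  expect_equal(unname(r$weighted), c(1, 1, 1))
  expect_equal(r$accuracy, 1)
  expect_equal(sum(r$confusion) - sum(diag(r$confusion)), 0)
})

test_that("metrics match hand arithmetic on a printed confusion matrix", {
  cm <- matrix(c(8, 2, 0,
                 1, 9, 0,
                 0, 0, 10), nrow = 3, byrow = TRUE)
  v <- labels_from_confusion(cm)
  r <- classification_report(v$true, v$pred)
  expect_equal(unname(r$per_class$recall), c(0.8, 0.9, 1.0))
  expect_equal(unname(r$per_class$precision), c(8 / 9, 9 / 11, 1.0))
  f1_high <- 2 * (8 / 9) * 0.8 / ((8 / 9) + 0.8)
  expect_equal(r$per_class$f1[1], f1_high)
  expect_equal(unname(r$weighted[["recall"]]), (8 + 9 + 10) / 30)
  # micro-averaged recall equals overall accuracy
  expect_equal(sum(r$per_class$recall * r$per_class$support) / 30, r$accuracy)
  # confusion row sums equal the true class counts
  expect_equal(unname(rowSums(r$confusion)), c(10, 10, 10))
})

test_that("weighted metrics are invariant to a consistent relabeling", {
  set.seed(1)
  true <- sample(c("HIGH", "MEDIUM", "LOW"), 60, replace = TRUE)
  pred <- sample(c("HIGH", "MEDIUM", "LOW"), 60, replace = TRUE)
  r1 <- classification_report(true, pred)
  perm <- c(HIGH = "LOW", MEDIUM = "HIGH", LOW = "MEDIUM")
  r2 <- classification_report(perm[true], perm[pred])
  expect_equal(r1$weighted[["f1"]], r2$weighted[["f1"]])
  expect_equal(r1$accuracy, r2$accuracy)
})

test_that("never-predicted classes get zero precision with a warning", {
  true <- c("HIGH", "HIGH", "LOW", "LOW")
  pred <- c("HIGH", "HIGH", "HIGH", "HIGH")
  expect_warning(r <- classification_report(true, pred), "never predicted")
  expect_equal(r$per_class$precision[3], 0)
  expect_error(classification_report(true, pred[1:3]), "lengths differ")
})

test_that("RR-interval estimation recovers configured rates on clean signals", {
  for (rate in c(110, 130, 150)) {
    cfg <- synthesis_config(duration = 12, fetal_rate = rate,
                            noise_amplitude_ratio = 0.02, seed = rate)
    rec <- preprocess_recording(generate_recording(cfg))
    segs <- segment_signal(rec)
    # interior segments only: the FIR ramp-in/out attenuates the first and
    # last window of a short recording
    segs <- segs[2:(length(segs) - 1)]
    est <- vapply(segs, estimate_frri, numeric(1))
    fhr <- 60 * 1000 / mean(est, na.rm = TRUE)
    expect_lt(abs(fhr - rate) / rate, 0.05)
    if (rate == 150) {
      expect_true(all(abs(est[!is.na(est)] - 400) <= 20))
    }
  }
  expect_true(is.na(estimate_frri(numeric(3000), fs = 1000)))
})

test_that("error metrics follow their closed forms", {
  expect_equal(rmse_frri(c(400, 500), c(410, 480)), sqrt((100 + 400) / 2))
  expect_equal(rmse_frri(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse_frri(400, 410), 10)
  expect_error(rmse_frri(numeric(0), numeric(0)), "empty")
  expect_error(rmse_frri(c(1, NA), c(1, 2)), "missing")

  expect_equal(aae_fhr(500, 400, fs = 1000), 30)
  expect_equal(aae_fhr(c(400, 500), c(400, 500), fs = 1000), 0)
  # halving each FHR error halves the AAE
  ref <- c(400, 480)
  est1 <- 60 * 1000 / (60 * 1000 / ref + c(10, -6))
  est2 <- 60 * 1000 / (60 * 1000 / ref + c(5, -3))
  expect_equal(aae_fhr(est1, ref, 1000) / 2, aae_fhr(est2, ref, 1000),
               tolerance = 1e-12)
  expect_error(aae_fhr(-400, 400, 1000), "positive")

  expect_equal(removal_rate(c(TRUE, TRUE, rep(FALSE, 8))), 0.2)
  expect_equal(removal_rate(rep(FALSE, 5)), 0)
  expect_equal(removal_rate(rep(TRUE, 5)), 1)
  expect_error(removal_rate(logical(0)), "empty")
})
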