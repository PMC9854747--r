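test_that("synthesis_config validates fields and names the offender", {
  expect_s3_class(synthesis_config(), "fecg_synthesis_config")
  expect_error(synthesis_config(duration = 0), "duration")
  expect_error(synthesis_config(fetal_rate = 20), "fetal_rate")
  expect_error(synthesis_config(maternal_rate = 400), "maternal_rate")
  expect_error(synthesis_config(noise_amplitude_ratio = -0.1),
               "noise_amplitude_ratio")
})

test_that("generate_recording has the right length and is seed-deterministic", {
  cfg <- synthesis_config(duration = 60, sampling_frequency = 1000, seed = 7)
  rec <- generate_recording(cfg)
  expect_length(rec$samples, 60000)
  expect_identical(rec$samples, generate_recording(cfg)$samples)
  cfg2 <- synthesis_config(duration = 60, seed = 8)
  expect_false(identical(rec$samples, generate_recording(cfg2)$samples))
})

test_that("clean recording carries the configured number of fetal QRS peaks", {
  cfg <- synthesis_config(duration = 60, fetal_rate = 140,
                          noise_amplitude_ratio = 0,
                          baseline_wander_amplitude = 0, seed = 3)
  rec <- generate_recording(cfg)
  x <- rec$samples
  thr <- 0.5 * max(x)
  peaks <- 0
  for (i in 2:(length(x) - 1)) {
    if (x[i] > thr && x[i] >= x[i - 1] && x[i] > x[i + 1]) peaks <- peaks + 1
  }
  expect_gte(peaks, 135)
  expect_lte(peaks, 145)
})

test_that("quality dataset is balanced, labeled and deterministic", {
  ds <- generate_quality_dataset(4, seed = 9, duration = 12)
  expect_length(ds$segments, 12)
  expect_equal(as.numeric(table(ds$labels)), c(4, 4, 4))
  expect_identical(levels(ds$labels), c("HIGH", "MEDIUM", "LOW"))

  ds2 <- generate_quality_dataset(4, seed = 9, duration = 12)
  expect_identical(ds$segments[[1]]$samples, ds2$segments[[1]]$samples)

  ds1 <- generate_quality_dataset(1, seed = 1, duration = 6)
  expect_length(ds1$segments, 3)

  expect_error(generate_quality_dataset(0, seed = 1), "n_per_class")
})

test_that("HIGH segments have lower noise-to-QRS ratio than LOW segments", {
  ds <- fx_small_dataset()
  ratios <- vapply(ds$segments, function(s) s$noise_ratio, numeric(1))
  expect_lt(mean(ratios[ds$labels == "HIGH"]),
            mean(ratios[ds$labels == "LOW"]))
  # and the per-segment ratios respect the class construction ranges
  expect_lt(max(ratios[ds$labels == "HIGH"]), 0.1)
  expect_gt(min(ratios[ds$labels == "LOW"]), 0.5)
})

test_that("unbalanced class counts are honoured", {
  ds <- generate_quality_dataset(c(HIGH = 5, MEDIUM = 3, LOW = 2),
                                 seed = 2, duration = 12)
  expect_equal(as.numeric(table(ds$labels)), c(5, 3, 2))
})
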