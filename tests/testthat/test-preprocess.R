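test_that("center_normalize maps to zero mean and unit peak", {
  expect_equal(center_normalize(c(1, 2, 3)), c(-1, 0, 1))
  expect_error(center_normalize(c(5, 5, 5)), "degenerate")
  set.seed(1)
  x <- center_normalize(rnorm(500, mean = 3, sd = 10))
  expect_equal(mean(x), 0, tolerance = 1e-12)
  expect_equal(max(abs(x)), 1)
})

test_that("band-pass keeps in-band power and rejects out-of-band power", {
  fs <- 1000
  t <- seq(0, 30, by = 1 / fs)
  in_band <- sin(2 * pi * 10 * t)
  y <- bandpass_filter(in_band, fs)
  expect_length(y, length(in_band))
  expect_gte(mean(y^2), 0.9 * mean(in_band^2))

  out_band <- sin(2 * pi * 0.3 * t)
  y2 <- bandpass_filter(out_band, fs)
  expect_lte(mean(y2^2), 0.05 * mean(out_band^2))

  expect_equal(bandpass_filter(numeric(5000), fs), numeric(5000))
  expect_error(bandpass_filter(in_band, fs, low = 46, high = 2), "band")
  expect_error(bandpass_filter(in_band, fs, low = 2, high = 600), "band")
})

test_that("despiking replaces outliers and nothing else", {
  x <- rep(1, 1000)
  x[500] <- 50
  y <- remove_spikes(x, window = 201, threshold_sds = 5)
  expect_equal(y[500], 1)
  expect_identical(y[-500], x[-500])

  t <- seq(0, 2, by = 1e-3)
  sine <- sin(2 * pi * 10 * t)
  expect_identical(remove_spikes(sine, 201, 5), sine)

  x2 <- sin(2 * pi * 5 * t)
  x2[c(800, 801)] <- c(30, -25)  # adjacent spikes narrower than window/2
  y2 <- remove_spikes(x2, 201, 5)
  expect_lt(max(abs(y2[c(800, 801)])), 2)
  expect_identical(y2, oracle_despike(x2, 201, 5))

  set.seed(4)
  x3 <- rnorm(3000)
  x3[sample(3000, 5)] <- 40
  expect_identical(remove_spikes(x3, 201, 5), oracle_despike(x3, 201, 5))

  expect_error(remove_spikes(x3, window = 200), "odd")
})

test_that("segmentation emits full windows on the hop grid", {
  fs <- 1000
  segs <- segment_signal(numeric(60 * fs), fs = fs)
  expect_length(segs, 39)
  expect_equal(vapply(segs, function(s) s$start_time, numeric(1)),
               seq(0, by = 1.5, length.out = 39))
  expect_true(all(vapply(segs, function(s) length(s$samples), numeric(1)) ==
                    3000))

  expect_length(segment_signal(numeric(3 * fs), fs = fs), 1)
  expect_warning(none <- segment_signal(numeric(2900), fs = fs), "shorter")
  expect_length(none, 0)
})

test_that("segmenting after filtering equals filtering then segmenting", {
  cfg <- synthesis_config(duration = 12, seed = 15)
  rec <- generate_recording(cfg)
  filtered <- bandpass_filter(center_normalize(rec))
  segs <- segment_signal(filtered)
  i0 <- round(1.5 * rec$sampling_frequency) + 1
  expect_identical(segs[[2]]$samples,
                   filtered$samples[i0:(i0 + 2999)])
})

test_that("spectrogram images have the contracted shape and are pure", {
  ds <- fx_small_dataset()
  seg <- ds$segments[[1]]
  sp <- make_spectrogram(seg)
  expect_equal(dim(sp$pixels), c(128, 128, 3))
  expect_true(all(sp$pixels >= 0 & sp$pixels <= 1))
  sp2 <- make_spectrogram(seg)
  expect_identical(sp$pixels, sp2$pixels)

  zero_seg <- structure(list(samples = numeric(3000),
                             sampling_frequency = 1000, start_time = 0,
                             label = NULL, id = "z"),
                        class = "fecg_segment")
  spz <- make_spectrogram(zero_seg)
  for (ch in 1:3) expect_equal(diff(range(spz$pixels[, , ch])), 0)

  expect_error(make_spectrogram(seg, band = c(2, 600)), "Nyquist")
})

test_that("spectrogram energy concentrates at the tone frequency", {
  fs <- 1000
  tone <- sin(2 * pi * 30 * seq(0, 3, by = 1 / fs))[1:3000]
  sm <- spectrogram_matrix(tone, fs = fs)
  peak_freq <- sm$freqs[which.max(rowMeans(sm$values))]
  expect_lt(abs(peak_freq - 30), 2)
})
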