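# Pre-processing chain: center/normalize -> band-pass -> despike ->
# segment -> spectrogram. The order is fixed; segments are always cut from
# the fully filtered recording, never filtered individually.

map_samples <- function(x, f) {
  if (inherits(x, "fecg_recording") || inherits(x, "fecg_segment")) {
    x$samples <- f(x$samples, x$sampling_frequency)
    return(x)
  }
  f(as.numeric(x), NULL)
}

get_fs <- function(x, fs) {
  if (inherits(x, "fecg_recording") || inherits(x, "fecg_segment")) {
    return(x$sampling_frequency)
  }
  if (is.null(fs)) stopf("'fs' is required for plain numeric input")
  fs
}

#' Center and normalize a recording to [-1, 1]
#'
#' Subtracts the mean and divides by the maximum absolute value, so the
#' output has zero mean and peak amplitude exactly 1.
#'
#' @param x numeric vector, `fecg_recording` or `fecg_segment`.
#' @return same type as the input, with transformed samples.
#' @export
center_normalize <- function(x) {
  map_samples(x, function(s, fs) {
    if (length(s) == 0) stopf("empty signal")
    s <- s - mean(s)
    m <- max(abs(s))
    if (m == 0) stopf("degenerate signal: all samples are equal")
    s / m
  })
}

# Kaiser-window FIR band-pass design. Length follows the standard Kaiser
# formula for the requested stopband attenuation and transition width.
design_bandpass_fir <- function(fs, low, high, transition_hz = 1,
                                atten_db = 60) {
  if (!(low < high && high < fs / 2)) {
    stopf("invalid band: need low < high < fs/2 (got [%g, %g] at fs = %g)",
          low, high, fs)
  }
  beta <- if (atten_db > 50) {
    0.1102 * (atten_db - 8.7)
  } else if (atten_db >= 21) {
    0.5842 * (atten_db - 21)^0.4 + 0.07886 * (atten_db - 21)
  } else {
    0
  }
  dw <- 2 * pi * transition_hz / fs
  len <- ceiling((atten_db - 7.95) / (2.285 * dw)) + 1
  if (len %% 2 == 0) len <- len + 1  # odd length: type-I linear phase
  win <- signal::kaiser(len, beta)
  signal::fir1(len - 1, c(low, high) / (fs / 2), type = "pass", window = win,
               scale = TRUE)
}

#' Linear-phase Kaiser band-pass filter
#'
#' Zero-mean FIR band-pass with a Kaiser window (60 dB stopband, 1 Hz
#' transition width by default), applied by FFT convolution with the group
#' delay compensated so the output is aligned with (and the same length as)
#' the input.
#'
#' @param x numeric vector, `fecg_recording` or `fecg_segment`.
#' @param fs sampling frequency in Hz (taken from the object when `x` is a
#'   recording or segment).
#' @param low,high band edges in Hz; must satisfy `low < high < fs/2`.
#' @param transition_hz transition bandwidth of the FIR design in Hz.
#' @param atten_db stopband attenuation in dB.
#' @return same type as the input, filtered.
#' @export
bandpass_filter <- function(x, fs = NULL, low = 2, high = 46,
                            transition_hz = 1, atten_db = 60) {
  fs_val <- get_fs(x, fs)
  b <- design_bandpass_fir(fs_val, low, high, transition_hz, atten_db)
  delay <- (length(b) - 1) / 2
  map_samples(x, function(s, ignored) {
    n <- length(s)
    full <- stats::convolve(s, rev(b), type = "open")
    full[(delay + 1):(delay + n)]
  })
}

#' Running-median spike removal
#'
#' Samples deviating from their running median by more than a robust
#' threshold are replaced by the running median; all other samples are left
#' untouched. The threshold is `threshold_sds` robust standard deviations
#' (1.4826 times the median absolute deviation of the residuals), floored at
#' `protect_factor` times the 99th percentile of the absolute residuals.
#' The floor matters for clean recordings: there the median absolute
#' deviation reflects only the noise floor, far below the QRS amplitude, and
#' a pure MAD rule would clip the very heartbeats the pipeline is meant to
#' assess. QRS complexes occupy a few percent of samples and therefore sit
#' inside the 99th percentile; genuine spikes are rarer and larger, so they
#' stay above the floor and are removed.
#'
#' @param x numeric vector, `fecg_recording` or `fecg_segment`.
#' @param window running-median window in samples; odd, at least 3.
#' @param threshold_sds replacement threshold in robust standard deviations.
#' @param protect_factor multiplier of the 99th-percentile residual below
#'   which no sample is ever replaced.
#' @return same type as the input, despiked.
#' @export
remove_spikes <- function(x, window = 201, threshold_sds = 5,
                          protect_factor = 1.5) {
  if (window < 3 || window %% 2 == 0) {
    stopf("'window' must be odd and >= 3")
  }
  map_samples(x, function(s, fs) {
    if (length(s) <= window) return(s)
    med <- stats::runmed(s, window, endrule = "median")
    dev <- s - med
    scale <- 1.4826 * stats::median(abs(dev))
    threshold <- max(threshold_sds * scale,
                     protect_factor * stats::quantile(abs(dev), 0.99))
    out <- s
    bad <- abs(dev) > threshold
    out[bad] <- med[bad]
    out
  })
}

#' Cut a recording into sliding-window segments
#'
#' Slides a `window`-second window with `window - overlap` seconds of hop
#' over the recording, emitting only complete windows. Segment start times
#' are exact multiples of the hop, beginning at 0.
#'
#' @param x numeric vector or `fecg_recording`.
#' @param fs sampling frequency in Hz (ignored for recordings).
#' @param window window length in seconds.
#' @param overlap overlap between consecutive windows in seconds.
#' @return list of `fecg_segment` objects (empty, with a warning, when the
#'   recording is shorter than one window).
#' @examples
#' rec <- generate_recording(synthesis_config(duration = 60, seed = 1))
#' length(segment_signal(rec))  # 39 segments
#' @export
segment_signal <- function(x, fs = NULL, window = 3, overlap = 1.5) {
  if (overlap >= window) stopf("'overlap' must be smaller than 'window'")
  fs_val <- get_fs(x, fs)
  s <- as_samples(x)
  hop <- window - overlap
  dur <- length(s) / fs_val
  if (dur < window) {
    warning("recording shorter than one window: returning no segments")
    return(list())
  }
  n_seg <- floor((dur - window) / hop) + 1
  win_n <- round(window * fs_val)
  lapply(seq_len(n_seg) - 1, function(k) {
    start <- k * hop
    i0 <- round(start * fs_val) + 1L
    structure(list(
      samples = s[i0:(i0 + win_n - 1L)],
      sampling_frequency = fs_val,
      start_time = start,
      label = NULL,
      id = sprintf("seg_t%08.2f", start)
    ), class = "fecg_segment")
  })
}

# Fixed 256 x 3 colormap lookup table (perceptually uniform), built once from
# grDevices so rendering is reproducible across platforms.
viridis_lut <- local({
  lut <- NULL
  function() {
    if (is.null(lut)) {
      cols <- grDevices::hcl.colors(256, "viridis")
      lut <<- t(grDevices::col2rgb(cols)) / 255
    }
    lut
  }
})

# Bilinear resize of a matrix to out_h x out_w.
resize_bilinear <- function(m, out_h, out_w) {
  in_h <- nrow(m)
  in_w <- ncol(m)
  ri <- if (in_h == 1) rep(1, out_h) else (seq_len(out_h) - 1) * (in_h - 1) / (out_h - 1) + 1
  ci <- if (in_w == 1) rep(1, out_w) else (seq_len(out_w) - 1) * (in_w - 1) / (out_w - 1) + 1
  r0 <- pmin(floor(ri), in_h - 1L); r0 <- pmax(r0, 1L)
  c0 <- pmin(floor(ci), in_w - 1L); c0 <- pmax(c0, 1L)
  fr <- ri - r0
  fc <- ci - c0
  if (in_h == 1) { r0 <- rep(1L, out_h); fr <- rep(0, out_h) }
  if (in_w == 1) { c0 <- rep(1L, out_w); fc <- rep(0, out_w) }
  a <- m[r0, c0, drop = FALSE]
  b <- m[pmin(r0 + 1L, in_h), c0, drop = FALSE]
  cc <- m[r0, pmin(c0 + 1L, in_w), drop = FALSE]
  d <- m[pmin(r0 + 1L, in_h), pmin(c0 + 1L, in_w), drop = FALSE]
  fr_m <- matrix(fr, out_h, out_w)
  fc_m <- matrix(fc, out_h, out_w, byrow = TRUE)
  a * (1 - fr_m) * (1 - fc_m) + b * fr_m * (1 - fc_m) +
    cc * (1 - fr_m) * fc_m + d * fr_m * fc_m
}

#' Band-limited STFT magnitude matrix of a segment
#'
#' Computes the short-time Fourier transform with the stated window and step,
#' restricts the rows to the requested frequency band, converts magnitude to
#' decibels with a 60 dB floor below the per-image maximum and min-max
#' normalizes to [0, 1].
#'
#' @param segment `fecg_segment` or numeric vector.
#' @param fs sampling frequency (Hz), ignored for segments.
#' @param stft_window STFT window length in seconds.
#' @param step STFT hop in seconds.
#' @param band `c(low, high)` frequency band in Hz to retain.
#' @param db_floor dynamic range in dB retained below the maximum.
#' @return list with `values` (frequency x time matrix in [0, 1]), `freqs`
#'   and `times`.
#' @export
spectrogram_matrix <- function(segment, fs = NULL, stft_window = 0.128,
                               step = 0.005, band = c(2, 60), db_floor = 60) {
  fs_val <- get_fs(segment, fs)
  x <- as_samples(segment)
  if (band[2] > fs_val / 2) {
    stopf("spectrogram band [%g, %g] Hz exceeds the Nyquist frequency %g Hz",
          band[1], band[2], fs_val / 2)
  }
  win_n <- round(stft_window * fs_val)
  if (win_n >= length(x)) stopf("STFT window must be shorter than the segment")
  step_n <- max(1L, round(step * fs_val))
  nfft <- 4 * 2^ceiling(log2(win_n))  # zero-padded for a finer frequency grid
  sg <- signal::specgram(x, n = nfft, Fs = fs_val,
                         window = signal::hanning(win_n),
                         overlap = win_n - step_n)
  keep <- sg$f >= band[1] & sg$f <= band[2]
  mag <- abs(sg$S[keep, , drop = FALSE])
  db <- 20 * log10(mag + 1e-12)
  db <- pmax(db, max(db) - db_floor)
  rng <- range(db)
  denom <- if (diff(rng) > 0) diff(rng) else 1
  list(values = (db - rng[1]) / denom, freqs = sg$f[keep], times = sg$t)
}

#' Render a segment as a fixed-size 3-channel spectrogram image
#'
#' Maps the normalized STFT magnitude matrix of [spectrogram_matrix()]
#' through a fixed 256-entry perceptually uniform colormap and bilinearly
#' resizes each channel to `size` x `size`. The rendering is a pure,
#' deterministic function of the segment: identical segments give identical
#' images. Degenerate (e.g. all-zero) segments produce a uniform image.
#'
#' @inheritParams spectrogram_matrix
#' @param size output image side length in pixels.
#' @return object of class `fecg_spectrogram`: list with `pixels`
#'   (`size x size x 3` array in [0, 1]), `frequency_range` and `time_range`.
#' @export
make_spectrogram <- function(segment, fs = NULL, stft_window = 0.128,
                             step = 0.005, band = c(2, 60), size = 128) {
  sm <- spectrogram_matrix(segment, fs = fs, stft_window = stft_window,
                           step = step, band = band)
  lut <- viridis_lut()
  idx <- pmin(255L, as.integer(floor(sm$values * 256))) + 1L
  pixels <- array(0, dim = c(size, size, 3))
  for (ch in 1:3) {
    channel <- matrix(lut[idx, ch], nrow = nrow(sm$values))
    pixels[, , ch] <- resize_bilinear(channel, size, size)
  }
  pixels[pixels < 0] <- 0
  pixels[pixels > 1] <- 1
  structure(list(
    pixels = pixels,
    frequency_range = range(sm$freqs),
    time_range = range(sm$times)
  ), class = "fecg_spectrogram")
}

#' Standard pre-processing chain for a recording
#'
#' Applies, in fixed order: centering/normalization to [-1, 1], Kaiser
#' band-pass filtering, and running-median spike removal.
#'
#' @param recording `fecg_recording` (or numeric vector with `fs`).
#' @param fs sampling frequency for numeric input.
#' @param low,high band-pass edges in Hz.
#' @param spike_window,spike_threshold despiking parameters; see
#'   [remove_spikes()].
#' @return processed object of the same type.
#' @export
preprocess_recording <- function(recording, fs = NULL, low = 2, high = 46,
                                 spike_window = 201, spike_threshold = 5) {
  out <- center_normalize(recording)
  out <- bandpass_filter(out, fs = fs, low = low, high = high)
  remove_spikes(out, window = spike_window, threshold_sds = spike_threshold)
}
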