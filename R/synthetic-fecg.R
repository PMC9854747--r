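# Synthetic abdominal-FECG generation.
#
# Real abdominal FECG is dominated by the maternal ECG, with the fetal QRS
# visible as a faster train of much smaller sharp deflections, on top of
# baseline wander and broadband measurement noise. The generator emulates
# exactly those ingredients so the quality-assessment pipeline can be
# exercised end to end with known ground truth (beat times, noise level,
# quality class).

#' Synthesis configuration for a synthetic abdominal-FECG recording
#'
#' @param duration recording length in seconds.
#' @param sampling_frequency sampling rate in Hz.
#' @param fetal_rate fetal heart rate in beats/min (must lie in (30, 300)).
#' @param maternal_rate maternal heart rate in beats/min (must lie in
#'   (30, 300)).
#' @param fetal_amplitude peak amplitude of the fetal QRS-like wavelet
#'   (arbitrary units; the reference amplitude for `noise_amplitude_ratio`).
#' @param maternal_amplitude peak amplitude of the maternal component.
#' @param noise_amplitude_ratio peak noise amplitude divided by the fetal QRS
#'   peak amplitude. `0` yields a noise-free recording; values near `1` put
#'   the noise amplitude close to the heartbeat amplitude (the low-quality
#'   regime).
#' @param baseline_wander_amplitude amplitude of the sub-1 Hz sinusoidal
#'   baseline drift.
#' @param rr_jitter_sd standard deviation (seconds) of the per-beat jitter
#'   added to the fetal RR interval.
#' @param include_maternal logical; add the maternal ECG component. The
#'   default `FALSE` emulates recordings after maternal-ECG cancellation,
#'   which is the signal the quality pipeline normally consumes.
#' @param burst_rate expected number of transient high-amplitude artifact
#'   bursts per minute (electrode-motion-like); `0` disables bursts.
#' @param burst_amplitude_ratio burst peak amplitude divided by the fetal QRS
#'   peak amplitude.
#' @param seed integer seed; identical configurations (including seed) yield
#'   bit-identical recordings.
#' @return an object of class `fecg_synthesis_config`.
#' @export
synthesis_config <- function(duration = 60,
                             sampling_frequency = 1000,
                             fetal_rate = 140,
                             maternal_rate = 75,
                             fetal_amplitude = 1,
                             maternal_amplitude = 2.5,
                             noise_amplitude_ratio = 0.1,
                             baseline_wander_amplitude = 0.1,
                             rr_jitter_sd = 0.01,
                             include_maternal = FALSE,
                             burst_rate = 0,
                             burst_amplitude_ratio = 2,
                             seed = 1L) {
  check_number(duration, "duration", lower = 0, strict_lower = TRUE)
  check_number(sampling_frequency, "sampling_frequency", lower = 0,
               strict_lower = TRUE)
  check_number(fetal_rate, "fetal_rate", lower = 30, upper = 300,
               strict_lower = TRUE, strict_upper = TRUE)
  check_number(maternal_rate, "maternal_rate", lower = 30, upper = 300,
               strict_lower = TRUE, strict_upper = TRUE)
  check_number(fetal_amplitude, "fetal_amplitude", lower = 0,
               strict_lower = TRUE)
  check_number(maternal_amplitude, "maternal_amplitude", lower = 0)
  check_number(noise_amplitude_ratio, "noise_amplitude_ratio", lower = 0)
  check_number(baseline_wander_amplitude, "baseline_wander_amplitude",
               lower = 0)
  check_number(rr_jitter_sd, "rr_jitter_sd", lower = 0)
  check_number(burst_rate, "burst_rate", lower = 0)
  check_number(burst_amplitude_ratio, "burst_amplitude_ratio", lower = 0)
  if (!is.logical(include_maternal) || length(include_maternal) != 1) {
    stopf("'include_maternal' must be TRUE or FALSE")
  }
  structure(list(
    duration = duration,
    sampling_frequency = sampling_frequency,
    fetal_rate = fetal_rate,
    maternal_rate = maternal_rate,
    fetal_amplitude = fetal_amplitude,
    maternal_amplitude = maternal_amplitude,
    noise_amplitude_ratio = noise_amplitude_ratio,
    baseline_wander_amplitude = baseline_wander_amplitude,
    rr_jitter_sd = rr_jitter_sd,
    include_maternal = include_maternal,
    burst_rate = burst_rate,
    burst_amplitude_ratio = burst_amplitude_ratio,
    seed = as.integer(seed)
  ), class = "fecg_synthesis_config")
}

# Mexican-hat (Ricker) wavelet: (1 - t^2/sigma^2) exp(-t^2 / (2 sigma^2)).
# Peak value 1 at t = 0, zero crossings at +/- sigma: a biphasic spike whose
# central lobe width (2 sigma) plays the role of the QRS duration.
ricker_wavelet <- function(sigma, fs) {
  half <- ceiling(4 * sigma * fs)
  t <- (-half:half) / fs
  (1 - (t / sigma)^2) * exp(-t^2 / (2 * sigma^2))
}

# Superpose one wavelet per beat time onto a zero signal of n samples.
pulse_train <- function(beat_times, wavelet, amplitude, n, fs) {
  x <- numeric(n)
  half <- (length(wavelet) - 1L) / 2L
  centers <- round(beat_times * fs) + 1L
  for (c0 in centers) {
    i0 <- c0 - half
    i1 <- c0 + half
    j0 <- max(1L, i0)
    j1 <- min(n, i1)
    if (j0 > j1) next
    x[j0:j1] <- x[j0:j1] + amplitude * wavelet[(j0 - i0 + 1L):(j1 - i0 + 1L)]
  }
  x
}

draw_beat_times <- function(rate_bpm, duration, jitter_sd) {
  mean_rr <- 60 / rate_bpm
  t <- stats::runif(1, 0, mean_rr)
  times <- numeric(0)
  while (t < duration) {
    times <- c(times, t)
    rr <- mean_rr + stats::rnorm(1, 0, jitter_sd)
    rr <- max(rr, 0.25 * mean_rr)
    t <- t + rr
  }
  times
}

#' Generate a synthetic abdominal-FECG recording
#'
#' Builds a recording as the sum of a fetal QRS-like pulse train (Mexican-hat
#' wavelets, ~40 ms wide, at the configured fetal rate with per-beat RR
#' jitter), an optional slower and stronger maternal component (~80 ms
#' wavelets), sinusoidal baseline wander below 1 Hz, band-limited (2-60 Hz)
#' Gaussian noise whose peak amplitude is `noise_amplitude_ratio` times the
#' fetal QRS peak, and optional rectangular-windowed artifact bursts.
#'
#' @param config a [synthesis_config()] object.
#' @param channel_id,subject_id identifiers stored in the recording metadata.
#' @return an object of class `fecg_recording`: a list with elements
#'   `samples`, `sampling_frequency`, `channel_id`, `subject_id`,
#'   `fetal_beat_times` (seconds), `maternal_beat_times`, `components`
#'   (the individual additive parts), and `config`.
#' @examples
#' rec <- generate_recording(synthesis_config(duration = 10, seed = 7))
#' length(rec$samples)  # 10 s at 1 kHz -> 10000 samples
#' @export
generate_recording <- function(config, channel_id = "ch1",
                               subject_id = "synthetic") {
  if (!inherits(config, "fecg_synthesis_config")) {
    stopf("'config' must be created by synthesis_config()")
  }
  fs <- config$sampling_frequency
  n <- round(config$duration * fs)
  with_seed(config$seed, {
    fetal_times <- draw_beat_times(config$fetal_rate, config$duration,
                                   config$rr_jitter_sd)
    fetal <- pulse_train(fetal_times, ricker_wavelet(0.020, fs),
                         config$fetal_amplitude, n, fs)

    maternal_times <- draw_beat_times(config$maternal_rate, config$duration,
                                      0.005)
    maternal <- if (config$include_maternal) {
      pulse_train(maternal_times, ricker_wavelet(0.040, fs),
                  config$maternal_amplitude, n, fs)
    } else {
      numeric(n)
    }

    bl_freq <- stats::runif(1, 0.15, 0.45)
    bl_phase <- stats::runif(1, 0, 2 * pi)
    t <- (seq_len(n) - 1) / fs
    baseline <- config$baseline_wander_amplitude *
      sin(2 * pi * bl_freq * t + bl_phase)

    noise <- numeric(n)
    if (config$noise_amplitude_ratio > 0) {
      raw <- stats::rnorm(n)
      raw <- bandpass_filter(raw, fs, low = 2, high = min(60, fs / 2 - 1))
      noise <- raw * (config$noise_amplitude_ratio * config$fetal_amplitude /
                        max(abs(raw)))
    }
    if (config$burst_rate > 0) {
      n_bursts <- stats::rpois(1, config$burst_rate * config$duration / 60)
      for (b in seq_len(n_bursts)) {
        len <- round(stats::runif(1, 0.2, 0.5) * fs)
        start <- sample.int(max(1L, n - len), 1)
        burst <- stats::rnorm(len)
        burst <- burst * (config$burst_amplitude_ratio *
                            config$fetal_amplitude / max(abs(burst)))
        idx <- start:(start + len - 1L)
        noise[idx] <- noise[idx] + burst
      }
    }

    structure(list(
      samples = fetal + maternal + baseline + noise,
      sampling_frequency = fs,
      channel_id = channel_id,
      subject_id = subject_id,
      fetal_beat_times = fetal_times,
      maternal_beat_times = maternal_times,
      components = list(fetal = fetal, maternal = maternal,
                        baseline = baseline, noise = noise),
      config = config
    ), class = "fecg_recording")
  })
}

#' @exportS3Method base::print
print.fecg_recording <- function(x, ...) {
  cat(sprintf("<fecg_recording> %d samples @ %g Hz (%.1f s), %d fetal beats\n",
              length(x$samples), x$sampling_frequency,
              length(x$samples) / x$sampling_frequency,
              length(x$fetal_beat_times)))
  invisible(x)
}

#' Default noise-ratio ranges for the three quality classes
#'
#' High quality means almost no visible noise; medium quality means noise
#' whose amplitude stays far below the heartbeat amplitude; low quality means
#' noise amplitude close to the heartbeat amplitude. The ranges map those
#' descriptions onto the generator's `noise_amplitude_ratio`.
#'
#' @return named list of `c(min, max)` ratio ranges for `HIGH`, `MEDIUM`,
#'   `LOW`.
#' @export
default_quality_noise_ranges <- function() {
  list(HIGH = c(0, 0.05), MEDIUM = c(0.15, 0.4), LOW = c(0.8, 1.2))
}

#' Generate a labeled synthetic quality dataset of 3 s segments
#'
#' Draws full recordings per quality class (one noise-amplitude ratio per
#' recording, sampled from that class's range), pre-processes each recording
#' with the standard chain (center/normalize, band-pass, despike), cuts it
#' into sliding-window segments, and returns the first `n_per_class` segments
#' of each class. Low-quality recordings additionally receive artifact
#' bursts. Each segment keeps its ground-truth fetal beat times and the
#' within-segment noise-to-QRS amplitude ratio computed from the generator's
#' internal components.
#'
#' @param n_per_class segments per class: a single count, or a named length-3
#'   vector with entries `HIGH`, `MEDIUM`, `LOW` for unbalanced sets.
#' @param seed integer seed controlling all randomness.
#' @param noise_ranges per-class `noise_amplitude_ratio` ranges; see
#'   [default_quality_noise_ranges()].
#' @param sampling_frequency,duration recording parameters (Hz, seconds).
#' @param window,overlap segmentation parameters in seconds.
#' @param fetal_rate_range fetal heart rates are drawn uniformly from this
#'   range (beats/min) per recording.
#' @param include_maternal add the maternal component (default `FALSE`,
#'   emulating extracted FECG).
#' @param low_burst_rate artifact bursts per minute injected into LOW-class
#'   recordings.
#' @param preprocess apply the standard pre-processing chain before
#'   segmentation (default `TRUE`).
#' @return an object of class `fecg_quality_dataset`: list with `segments`
#'   (list of `fecg_segment`), `labels` (quality factor), and `info`
#'   (data.frame with segment id, source recording, start time, label, noise
#'   ratio and fetal rate).
#' @examples
#' ds <- generate_quality_dataset(2, seed = 1, duration = 12)
#' table(ds$labels)
#' @export
generate_quality_dataset <- function(n_per_class, seed = 1L,
                                     noise_ranges = default_quality_noise_ranges(),
                                     sampling_frequency = 1000,
                                     duration = 60,
                                     window = 3,
                                     overlap = 1.5,
                                     fetal_rate_range = c(110, 160),
                                     include_maternal = FALSE,
                                     low_burst_rate = 6,
                                     preprocess = TRUE) {
  counts <- n_per_class
  if (length(counts) == 1) {
    counts <- stats::setNames(rep(counts, 3), quality_level_names)
  } else if (length(counts) == 3) {
    if (is.null(names(counts))) names(counts) <- quality_level_names
    counts <- counts[quality_level_names]
  } else {
    stopf("'n_per_class' must have length 1 or 3")
  }
  if (any(is.na(counts)) || any(counts < 1)) {
    stopf("'n_per_class' must be >= 1 for every class")
  }
  counts <- stats::setNames(as.integer(counts), quality_level_names)

  hop <- window - overlap
  segs_per_rec <- floor((duration - window) / hop) + 1
  if (segs_per_rec < 1) stopf("'duration' must be at least 'window'")

  n_recs <- ceiling(counts / segs_per_rec)
  plan <- with_seed(seed, {
    total <- sum(n_recs)
    list(seeds = sample.int(.Machine$integer.max - 1L, total),
         rates = stats::runif(total, fetal_rate_range[1], fetal_rate_range[2]),
         ratios = {
           r <- numeric(total)
           i <- 0
           for (cls in quality_level_names) {
             rng <- noise_ranges[[cls]]
             r[i + seq_len(n_recs[[cls]])] <-
               stats::runif(n_recs[[cls]], rng[1], rng[2])
             i <- i + n_recs[[cls]]
           }
           r
         })
  })

  segments <- list()
  labels <- character(0)
  info <- list()
  rec_idx <- 0
  for (cls in quality_level_names) {
    cls_segments <- list()
    cls_info <- list()
    for (r in seq_len(n_recs[[cls]])) {
      rec_idx <- rec_idx + 1
      cfg <- synthesis_config(
        duration = duration,
        sampling_frequency = sampling_frequency,
        fetal_rate = plan$rates[rec_idx],
        noise_amplitude_ratio = plan$ratios[rec_idx],
        include_maternal = include_maternal,
        burst_rate = if (cls == "LOW") low_burst_rate else 0,
        seed = plan$seeds[rec_idx]
      )
      rec <- generate_recording(cfg, subject_id = sprintf("rec%03d", rec_idx))
      proc <- if (preprocess) preprocess_recording(rec) else rec
      segs <- segment_signal(proc, window = window, overlap = overlap)
      fs <- rec$sampling_frequency
      for (s in segs) {
        t0 <- s$start_time
        t1 <- t0 + window
        in_win <- rec$fetal_beat_times >= t0 & rec$fetal_beat_times < t1
        idx <- (round(t0 * fs) + 1L):min(round(t1 * fs), length(rec$samples))
        qrs_peak <- max(abs(rec$components$fetal[idx]))
        noise_peak <- max(abs(rec$components$noise[idx]))
        s$label <- cls
        s$beat_times <- rec$fetal_beat_times[in_win] - t0
        s$noise_ratio <- if (qrs_peak > 0) noise_peak / qrs_peak else Inf
        s$id <- sprintf("%s_rec%03d_t%06.1f", cls, rec_idx, t0)
        cls_segments[[length(cls_segments) + 1L]] <- s
        cls_info[[length(cls_info) + 1L]] <- data.frame(
          segment_id = s$id, recording = rec_idx, start_s = t0,
          label = cls, noise_ratio = s$noise_ratio,
          fetal_rate = plan$rates[rec_idx], stringsAsFactors = FALSE
        )
      }
    }
    keep <- seq_len(counts[[cls]])
    segments <- c(segments, cls_segments[keep])
    labels <- c(labels, rep(cls, counts[[cls]]))
    info <- c(info, cls_info[keep])
  }

  structure(list(
    segments = segments,
    labels = quality_levels(labels),
    info = do.call(rbind, info)
  ), class = "fecg_quality_dataset")
}

#' @exportS3Method base::print
print.fecg_quality_dataset <- function(x, ...) {
  cat("<fecg_quality_dataset>\n")
  print(table(x$labels))
  invisible(x)
}
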