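# Twelve per-segment quality features. The eleven 1-D features below are
# computed from the processed time series; AE_MSE comes from the spectrogram
# autoencoder. Low-quality segments are more irregular (higher entropies,
# higher fractal dimension, heavier tails) and carry relatively less power in
# the QRS band, which is what these statistics measure.

#' Canonical feature order
#'
#' @return character vector with the twelve feature names in their fixed
#'   column order.
#' @export
feature_names <- function() {
  c("AppEn", "SampEn", "SpecEn", "PEn", "DFA", "FD", "HFD",
    "kSQI", "sSQI", "pSQI", "basSQI", "AE_MSE")
}

#' Entropy and ordinal-pattern parameters
#'
#' Standard defaults from the entropy literature: embedding dimension 2 and
#' tolerance 0.2 standard deviations for approximate/sample entropy, order 3
#' and delay 1 for permutation entropy. The tolerance is relative to the
#' per-segment standard deviation.
#'
#' @param m embedding dimension for approximate/sample entropy.
#' @param r tolerance as a fraction of the segment's standard deviation.
#' @param perm_order ordinal pattern length for permutation entropy.
#' @param perm_delay ordinal pattern delay in samples.
#' @return list of validated parameters.
#' @export
entropy_params <- function(m = 2, r = 0.2, perm_order = 3, perm_delay = 1) {
  check_number(m, "m", lower = 1)
  check_number(r, "r", lower = 0, strict_lower = TRUE)
  check_number(perm_order, "perm_order", lower = 2)
  check_number(perm_delay, "perm_delay", lower = 1)
  list(m = as.integer(m), r = r, perm_order = as.integer(perm_order),
       perm_delay = as.integer(perm_delay))
}

#' Approximate entropy
#'
#' Template-matching irregularity with self-matches included (Chebyshev
#' distance): `Phi_m - Phi_{m+1}`. Constant input returns 0.
#'
#' @param x numeric vector.
#' @param m embedding dimension.
#' @param r tolerance as a fraction of `sd(x)`.
#' @return approximate entropy (non-negative up to estimator noise).
#' @export
approximate_entropy <- function(x, m = 2, r = 0.2) {
  template_entropies(x, m, r)[1]
}

#' Sample entropy
#'
#' `-log(A/B)` with self-matches excluded (Chebyshev distance). Constant
#' input returns 0 by convention; when no templates match (A or B zero) the
#' value is `Inf`, which [extract_features()] replaces by a finite cap.
#'
#' @inheritParams approximate_entropy
#' @return sample entropy, possibly `Inf`.
#' @export
sample_entropy <- function(x, m = 2, r = 0.2) {
  template_entropies(x, m, r)[2]
}

# Both template entropies from one pass (they share all pair distances).
template_entropies <- function(x, m = 2, r = 0.2) {
  x <- as_samples(x)
  if (length(x) < m + 2) stopf("sequence too short for m = %d", m)
  s <- stats::sd(x)
  if (s == 0) return(c(0, 0))
  appen_sampen_cpp(x, as.integer(m), r * s)
}

# Welch power spectral density: Hann windows, 50% overlap, one-sided. The
# default window spans a whole 3 s segment (plain windowed periodogram);
# anything shorter cannot resolve the 0-1 Hz baseline band that basSQI
# integrates. Longer inputs get genuine Welch averaging.
welch_psd <- function(x, fs, window_sec = 3, overlap = 0.5) {
  n <- length(x)
  win_n <- min(n, round(window_sec * fs))
  hop <- max(1L, round(win_n * (1 - overlap)))
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(win_n) / (win_n + 1))
  starts <- seq(1L, n - win_n + 1L, by = hop)
  nfft <- win_n
  half <- floor(nfft / 2) + 1L
  acc <- numeric(half)
  for (s0 in starts) {
    seg <- x[s0:(s0 + win_n - 1L)] * w
    sp <- stats::fft(seg)[seq_len(half)]
    acc <- acc + (Mod(sp)^2) / (fs * sum(w^2))
  }
  psd <- acc / length(starts)
  # one-sided: double everything except DC (and Nyquist for even nfft)
  scale2 <- rep(2, half)
  scale2[1] <- 1
  if (nfft %% 2 == 0) scale2[half] <- 1
  list(freq = (seq_len(half) - 1L) * fs / nfft, psd = psd * scale2)
}

#' Spectral entropy
#'
#' Shannon entropy of the Welch power-spectral-density normalized to a
#' probability distribution, divided by the log of the number of bins, so the
#' value lies in [0, 1]: near 1 for a flat (noise-like) spectrum, near 0 for
#' a concentrated (tonal) one.
#'
#' @param x numeric vector.
#' @param fs sampling frequency in Hz.
#' @return normalized spectral entropy in [0, 1].
#' @export
spectral_entropy <- function(x, fs) {
  x <- as_samples(x)
  if (stats::sd(x) == 0) stopf("degenerate signal: constant input")
  w <- welch_psd(x - mean(x), fs)
  p <- w$psd / sum(w$psd)
  p <- p[p > 0]
  -sum(p * log(p)) / log(length(w$psd))
}

#' Permutation entropy
#'
#' Shannon entropy of ordinal-pattern frequencies normalized by
#' `log(order!)`, in [0, 1]. Ties within a pattern are broken by order of
#' appearance (stable ranking).
#'
#' @param x numeric vector.
#' @param order ordinal pattern length.
#' @param delay pattern delay in samples.
#' @return normalized permutation entropy in [0, 1].
#' @export
permutation_entropy <- function(x, order = 3, delay = 1) {
  x <- as_samples(x)
  n <- length(x)
  if (n < order * delay + 1) stopf("sequence too short for order %d", order)
  n_pat <- n - (order - 1) * delay
  # stable ranks, vectorized over all patterns: rank of element i =
  # #{j : x_j < x_i} + #{j < i : x_j == x_i} within each pattern
  emb <- vapply(0:(order - 1), function(k) x[seq_len(n_pat) + k * delay],
                numeric(n_pat))
  ranks <- matrix(0L, n_pat, order)
  for (i in seq_len(order)) {
    for (j in seq_len(order)) {
      if (i == j) next
      ranks[, i] <- ranks[, i] + (emb[, j] < emb[, i]) +
        (j < i) * (emb[, j] == emb[, i])
    }
  }
  code <- as.vector(ranks %*% (order + 1)^(seq_len(order) - 1))
  p <- tabulate(match(code, unique(code)))
  p <- p / n_pat
  -sum(p * log(p)) / log(factorial(order))
}

#' Detrended fluctuation analysis scaling exponent (DFA-1)
#'
#' Integrates the centered series, splits the profile into non-overlapping
#' boxes, removes a linear trend per box, and returns the slope of
#' `log F(s)` versus `log s` over ~16 logarithmically spaced box sizes from 4
#' to n/4. White noise gives an exponent near 0.5, a random walk near 1.5.
#'
#' @param x numeric vector of length at least 64.
#' @param n_scales number of box sizes on the log grid.
#' @return DFA scaling exponent (alpha).
#' @export
dfa_alpha <- function(x, n_scales = 16) {
  x <- as_samples(x)
  n <- length(x)
  if (n < 64) stopf("sequence too short for DFA (need >= 64 samples)")
  profile <- cumsum(x - mean(x))
  sizes <- unique(round(exp(seq(log(4), log(n / 4), length.out = n_scales))))
  fluct <- vapply(sizes, function(s) {
    n_box <- floor(n / s)
    X <- cbind(1, seq_len(s))
    proj <- X %*% solve(crossprod(X), t(X))
    segs <- matrix(profile[seq_len(n_box * s)], nrow = s)  # one box per column
    res <- segs - proj %*% segs
    sqrt(sum(res^2) / (n_box * s))
  }, numeric(1))
  keep <- fluct > 0
  stats::coef(stats::lm(log(fluct[keep]) ~ log(sizes[keep])))[[2]]
}

#' Katz fractal dimension
#'
#' `log10(n) / (log10(n) + log10(d / L))` where `L` is the summed absolute
#' successive difference (curve length), `d` the maximum distance from the
#' first sample, and `n = length(x) - 1`. Straight lines and constants give
#' exactly 1.
#'
#' @param x numeric vector of length at least 2.
#' @return Katz fractal dimension (>= 1 for sampled waveforms).
#' @export
katz_fd <- function(x) {
  x <- as_samples(x)
  if (length(x) < 2) stopf("need at least 2 samples")
  dists <- abs(diff(x))
  L <- sum(dists)
  if (L == 0) return(1)
  d <- max(abs(x - x[1]))
  n <- length(x) - 1
  log10(n) / (log10(n) + log10(d / L))
}

#' Higuchi fractal dimension
#'
#' Average normalized curve length `L(k)` over decimation factors
#' `k = 1..kmax`; the fractal dimension is the slope of `log L(k)` against
#' `log(1/k)`. Near 1 for smooth curves, near 2 for white noise.
#'
#' @param x numeric vector with `length(x) >= 10 * kmax`.
#' @param kmax maximum decimation factor.
#' @return Higuchi fractal dimension.
#' @export
higuchi_fd <- function(x, kmax = 10) {
  x <- as_samples(x)
  n <- length(x)
  if (n < 10 * kmax) stopf("sequence too short for kmax = %d", kmax)
  lk <- vapply(seq_len(kmax), function(k) {
    lm_sum <- 0
    for (m in seq_len(k)) {
      idx <- seq(m, n, by = k)
      nm <- length(idx)
      if (nm < 2) next
      lm_sum <- lm_sum + sum(abs(diff(x[idx]))) * (n - 1) / ((nm - 1) * k) / k
    }
    lm_sum / k
  }, numeric(1))
  keep <- lk > 0
  k <- seq_len(kmax)[keep]
  stats::coef(stats::lm(log(lk[keep]) ~ log(1 / k)))[[2]]
}

#' Kurtosis and skewness quality indices
#'
#' `kSQI` is the standardized fourth central moment (Pearson kurtosis, not
#' excess; 3 for a Gaussian); `sSQI` the standardized third central moment.
#' Clean ECG-like signals are strongly peaked (high kurtosis); Gaussian noise
#' drags kurtosis toward 3.
#'
#' @param x numeric vector, not constant.
#' @return named numeric vector with elements `kSQI` and `sSQI`.
#' @export
moment_sqis <- function(x) {
  x <- as_samples(x)
  m2 <- mean((x - mean(x))^2)
  if (m2 == 0) stopf("degenerate signal: constant input")
  m3 <- mean((x - mean(x))^3)
  m4 <- mean((x - mean(x))^4)
  c(kSQI = m4 / m2^2, sSQI = m3 / m2^1.5)
}

band_power <- function(w, lo, hi) {
  keep <- w$freq >= lo & w$freq <= hi
  if (sum(keep) < 2) return(sum(w$psd[keep]))
  pracma::trapz(w$freq[keep], w$psd[keep])
}

#' Relative QRS-band power (pSQI)
#'
#' Ratio of the 5-15 Hz band power to the 5-40 Hz band power of the Welch
#' periodogram. QRS energy concentrates around 10 Hz, so clean ECG yields
#' values well inside (0, 1) while broadband noise pushes the ratio down.
#'
#' @param x numeric vector.
#' @param fs sampling frequency in Hz (>= 80).
#' @return pSQI in [0, 1].
#' @export
psqi <- function(x, fs) {
  x <- as_samples(x)
  if (fs < 80) stopf("'fs' must be at least 80 Hz for the 5-40 Hz bands")
  if (stats::sd(x) == 0) stopf("degenerate signal: constant input")
  w <- welch_psd(x, fs)
  denom <- band_power(w, 5, 40)
  if (denom <= 0) stopf("degenerate signal: no power in 5-40 Hz")
  min(1, max(0, band_power(w, 5, 15) / denom))
}

#' Relative baseline power (basSQI)
#'
#' `1 - P(0-1 Hz) / P(0-40 Hz)`: close to 1 when baseline wander is absent,
#' close to 0 when nearly all power sits below 1 Hz.
#'
#' @inheritParams psqi
#' @return basSQI in [0, 1].
#' @export
bassqi <- function(x, fs) {
  x <- as_samples(x)
  if (fs < 80) stopf("'fs' must be at least 80 Hz for the 0-40 Hz bands")
  if (stats::sd(x) == 0) stopf("degenerate signal: constant input")
  w <- welch_psd(x, fs)
  denom <- band_power(w, 0, 40)
  if (denom <= 0) stopf("degenerate signal: no power in 0-40 Hz")
  min(1, max(0, 1 - band_power(w, 0, 1) / denom))
}

#' Extract the twelve quality features of one segment
#'
#' Computes the eleven time-series features from the processed 1-D segment
#' and the autoencoder reconstruction error (`AE_MSE`) from its spectrogram
#' image, in the fixed order of [feature_names()]. An infinite sample
#' entropy (no template matches) is replaced by the finite cap
#' `log((n-m) * (n-m-1) / 2)` (the log of the template-pair count) with a
#' warning, so downstream selection and classification receive finite
#' numbers.
#'
#' @param segment `fecg_segment` (or numeric vector with `fs`).
#' @param spectrogram `fecg_spectrogram` of the same segment.
#' @param ae trained autoencoder from [train_ae()].
#' @param params entropy parameters from [entropy_params()].
#' @param fs sampling frequency for numeric input.
#' @return named numeric vector of 12 finite features.
#' @export
extract_features <- function(segment, spectrogram, ae,
                             params = entropy_params(), fs = NULL) {
  fs_val <- get_fs(segment, fs)
  x <- as_samples(segment)
  n <- length(x)
  compute <- function(name, fun) {
    tryCatch(fun(), error = function(e) {
      stopf("feature %s: %s", name, conditionMessage(e))
    })
  }
  ent <- compute("AppEn/SampEn", function()
    template_entropies(x, params$m, params$r))
  if (!is.finite(ent[2])) {
    cap <- log((n - params$m) * (n - params$m - 1) / 2)
    warning(sprintf(
      "SampEn had no template matches; capped at log of pair count (%.3f)",
      cap))
    ent[2] <- cap
  }
  vals <- c(
    AppEn = ent[1],
    SampEn = ent[2],
    SpecEn = compute("SpecEn", function() spectral_entropy(x, fs_val)),
    PEn = compute("PEn", function()
      permutation_entropy(x, params$perm_order, params$perm_delay)),
    DFA = compute("DFA", function() dfa_alpha(x)),
    FD = compute("FD", function() katz_fd(x)),
    HFD = compute("HFD", function() higuchi_fd(x)),
    compute("kSQI/sSQI", function() moment_sqis(x)),
    pSQI = compute("pSQI", function() psqi(x, fs_val)),
    basSQI = compute("basSQI", function() bassqi(x, fs_val)),
    AE_MSE = compute("AE_MSE", function() ae_mse(ae, spectrogram))
  )
  names(vals) <- feature_names()
  vals
}

#' Feature matrix for a set of segments
#'
#' Applies [extract_features()] to every segment, returning a numeric matrix
#' with one row per segment and the twelve named feature columns.
#'
#' @param segments list of `fecg_segment` objects.
#' @param spectrograms list of matching `fecg_spectrogram` objects (computed
#'   with [make_spectrogram()] when omitted).
#' @param ae trained autoencoder.
#' @param params entropy parameters.
#' @param image_size spectrogram image side length when spectrograms are
#'   computed here; must match the autoencoder's input size.
#' @return numeric matrix (`length(segments)` x 12) with segment ids as row
#'   names.
#' @export
extract_feature_matrix <- function(segments, spectrograms = NULL, ae,
                                   params = entropy_params(),
                                   image_size = 128) {
  if (is.null(spectrograms)) {
    spectrograms <- lapply(segments, make_spectrogram, size = image_size)
  }
  stopifnot(length(segments) == length(spectrograms))
  rows <- mapply(function(s, sp) extract_features(s, sp, ae, params),
                 segments, spectrograms, SIMPLIFY = FALSE)
  X <- do.call(rbind, rows)
  rownames(X) <- vapply(segments, function(s)
    if (is.null(s$id)) "" else s$id, character(1))
  X
}
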