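---
title: "Unsupervised multi-level quality assessment for non-invasive fetal ECG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unsupervised multi-level quality assessment for non-invasive fetal ECG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Non-invasive fetal electrocardiography records the fetal heart from
electrodes on the maternal abdomen. The fetal QRS complexes are small, and
the recordings are routinely corrupted by maternal ECG residue, electrode
motion artifacts, baseline wander and broadband noise. Fetal heart rate
(FHR) estimates computed from corrupted stretches are unreliable, so a
practical monitoring pipeline needs to *grade* signal quality per short
segment and discard (or down-weight) the bad ones before estimating FHR.

Supervised quality classifiers need large annotated corpora, which rarely
exist for fetal ECG. `fecgsqa` implements an unsupervised alternative: a
self-organizing map (SOM) clusters segments in a feature space built from
twelve quality indicators, and only a handful of segments — three per SOM
neuron — ever need a human annotation.

## Pipeline

1. **Pre-processing** (`preprocess_recording()`): subtract the mean and
   scale to peak amplitude 1; band-pass 2–46 Hz with a linear-phase Kaiser
   FIR (60 dB stopband, 1 Hz transition width, group delay compensated);
   replace samples deviating from a 201-sample running median by more than 5
   robust standard deviations. The order is fixed, and segmentation always
   happens *after* filtering the whole recording, so segments are never
   filtered individually.
2. **Segmentation** (`segment_signal()`): 3 s windows, 1.5 s hop. Three
   seconds covers several fetal cardiac cycles at 110–160 beats/min, enough
   to expose periodicity, while staying short enough to localize artifacts.
3. **Spectrogram images** (`make_spectrogram()`): STFT with a 128 ms window
   and 5 ms step, rows restricted to 2–60 Hz, magnitude in dB with a 60 dB
   floor, per-image min–max normalization, a fixed 256-entry perceptually
   uniform colormap, bilinear resize to a square 3-channel image (128 px
   reference size). Any fixed, deterministic rendering works here — the
   autoencoder consumes whatever representation it was trained on — and this
   one is bit-reproducible.
4. **Autoencoder feature** (`build_ae()`, `train_ae()`, `ae_mse()`): a fully
   convolutional autoencoder with 3×3 kernels, filter sizes
   64, 32, 32, 32, 64, 1, 1, 64, 32, 32, 32, 64 and strides
   2, 2, 2, 2, 2, 1, 1, 2, 2, 2, 2, 2 across encoder and decoder, each
   followed by batch normalization and ELU, plus a stride-1 sigmoid output
   convolution. It is trained **only on high-quality spectrograms** with MSE
   loss, so low-quality inputs reconstruct poorly; the per-pixel mean squared
   reconstruction error (`AE_MSE`) is the twelfth quality feature.
5. **Eleven time-series features** (`extract_features()`): approximate and
   sample entropy (m = 2, r = 0.2 sd), normalized spectral entropy,
   permutation entropy (order 3, delay 1), the DFA-1 scaling exponent, Katz
   and Higuchi fractal dimensions, kurtosis and skewness, and the spectral
   quality ratios pSQI = P(5–15 Hz)/P(5–40 Hz) and
   basSQI = 1 − P(0–1 Hz)/P(0–40 Hz) from a Welch periodogram (Hann windows
   spanning the whole 3 s segment by default, 50 % overlap for longer
   inputs; shorter windows cannot resolve the 0–1 Hz baseline band that
   basSQI integrates).
6. **Feature selection** (`mcfs_scores()`, `select_top()`): multi-cluster
   feature selection — spectral embedding of a k-nearest-neighbor graph
   followed by a sparse regression of each embedding coordinate on the
   features; a feature's score is its largest absolute coefficient. The top
   5 features go to the classifier.
7. **Classification** (`train_som()`, `label_neurons()`, `classify()`): an
   8×8 SOM trained online for 100,000 iterations with initial learning rate
   0.5 and a bubble neighborhood; classes are balanced beforehand by random
   undersampling. Each neuron is labeled by the majority of three sampled
   winner segments; a fresh segment inherits its winning neuron's label.
8. **Evaluation** (`classification_report()`,
   `fhr_improvement_experiment()`): per-class precision/recall/F1 and the
   FHR experiment comparing RR-interval RMSE and mean absolute FHR error
   (AAE) with and without removing segments classified low-quality.

```{r}
library(fecgsqa)

ds <- generate_quality_dataset(100, seed = 1)
model <- fit_sqa_pipeline(ds, image_size = 64, ae_epochs = 6, seed = 1)
evaluate_sqa_model(model)
```

## The synthetic generator and what it does (not) show

The study data this method targets — 60 s abdominal recordings at 1 kHz with
expert three-level annotations — are proprietary, so the package ships a
generator (`generate_recording()`, `generate_quality_dataset()`) that
emulates their structure: fetal QRS-like Mexican-hat wavelets (~40 ms wide,
110–160 beats/min, per-beat RR jitter of 10 ms), an optional stronger and
slower maternal component (~80 ms wavelets; off by default, emulating
recordings after maternal-ECG cancellation), sinusoidal baseline wander
below 0.5 Hz, band-limited 2–60 Hz Gaussian noise, and rectangular
high-amplitude artifact bursts for the low-quality class.

Quality classes follow the annotation wording — high: almost no noise;
medium: noise amplitude far below the heartbeat amplitude; low: noise
amplitude close to the heartbeat amplitude — mapped to peak-noise-to-QRS
ratios of [0, 0.05], [0.15, 0.4] and [0.8, 1.2]. One ratio is drawn per
recording, so a class contains several distinct noise levels.

What passing tests on this generator show: the statistics are implemented
correctly (they match brute-force oracles and analytic limits), the
autoencoder learns the training distribution well enough for its
reconstruction error to order quality classes, the unsupervised selection
finds discriminative features, and the SOM recovers cluster structure that
is present in feature space. What they do **not** show: performance on real
abdominal FECG, whose noise is less stationary, whose classes overlap far
more, and whose morphology (P/T waves, maternal residue after imperfect
cancellation) the generator deliberately does not model. The synthetic
classes are well separated by construction, so near-perfect synthetic F1
scores say nothing about the F1 achievable on clinical data.

## Parameters that matter

| Parameter | Default | Why |
|---|---|---|
| band-pass edges | 2–46 Hz | covers fetal QRS energy; excludes wander and mains |
| FIR design | 60 dB, 1 Hz transition | Kaiser window; ~3.6 k taps at 1 kHz |
| despiking | 201 samples, 5 robust sd, 99th-percentile floor | window ≫ QRS width and the floor protects QRS peaks |
| window/hop | 3 s / 1.5 s | several cardiac cycles, 50 % overlap |
| STFT | 128 ms window, 5 ms step, 2–60 Hz | time–frequency detail at beat scale |
| entropy | m = 2, r = 0.2 sd | standard template-entropy defaults |
| permutation entropy | order 3, delay 1 | shortest informative ordinal patterns |
| AE training | Adam 1e-3, batch 64, sigmoid output | stable on [0,1] images |
| MCFS | 3 clusters, 5 neighbors, elastic net α = 0.5 | three quality levels; see below |
| SOM | 8×8, lr 0.5, 100 k iterations, bubble | quantization error plateaus here |
| selected features | top 5 | drops redundant/noisy indicators |

## Numerical and design choices

* **Eq.-style band ratios.** pSQI's integration bands are 5–15 Hz over
  5–40 Hz, read per the adult-ECG SQI literature; band integrals use the
  trapezoid rule on the Welch frequency grid.
* **Despiking rule.** The cited spike-removal method is not specified in
  detail anywhere accessible, so the package uses a documented running-median
  substitution (201 samples ≈ 200 ms; threshold 5×1.4826×MAD floored at 1.5
  times the 99th percentile of the residuals). The floor is essential on
  clean recordings, where the MAD reflects only the noise floor and a pure
  MAD rule would clip the QRS complexes themselves — which both distorts the
  features and makes downstream beat detection drop beats.
* **Spectrogram band vs filter band.** The recordings are band-passed at
  [2, 46] Hz but the spectrogram keeps [2, 60] Hz; rows above 46 Hz carry
  only stopband residue. Implemented exactly as stated, flagged here rather
  than "fixed".
* **Autoencoder output layer.** The printed filter list ends with a single
  filter, yet input and output are both 3-channel images; a 1-filter output
  cannot produce 3 channels, so the output convolution maps to the image
  channel count. All other filters/strides are verbatim.
* **Transposed convolutions** are implemented as zero-stuffed stride-1
  convolutions with 'same' padding, which makes each stride-2 decoder layer
  exactly double the spatial size (128→64→32→16→8→4 in the encoder and back
  in the decoder).
* **Batch-norm inference statistics** are the average batch statistics of
  the final training epoch — deterministic, and free of the warm-up bias of
  momentum-based running averages over few epochs.
* **Single-precision training.** The network is a feature extractor trained
  by stochastic gradient steps; float rounding is far below the optimization
  noise floor, and training determinism (same seed, same machine) is
  preserved.
* **Training epochs.** No canonical epoch count exists for this
  architecture; the default (Adam at 1e-3 for 50 epochs) is exposed, and the
  package's own experiments train until the loss trace visibly flattens. At
  the short schedules the tests use (~6 epochs on ~100 images, i.e. very few
  optimizer steps at batch 64), a larger step size (3e-3) is needed to reach
  the plateau; an autoencoder still in its optimization transient
  reconstructs everything poorly and its error does not yet order the
  quality classes.
* **MCFS specifics.** The heat-kernel bandwidth is the median distance over
  the realized kNN edges (a global all-pairs median is dominated by
  between-cluster distances and blurs the graph); the embedding keeps the
  `n_clusters` smallest Laplacian eigenvectors *including* the trivial one
  (the regression intercept absorbs it, and when the graph splits into
  components the whole null space carries the cluster indicators); the
  sparse regression is an elastic net (α = 0.5) read at the densest end of
  the path — pure L1 there is non-unique and would give duplicated features
  arbitrary score splits.
* **SOM decay schedules.** lr(t) = lr₀ / (1 + 2t/T); bubble radius decays
  linearly from half the grid to 1. Winner ties break to the
  lexicographically smallest (row, column); a three-way label tie resolves
  toward LOW, the conservative choice when the goal is removing bad
  segments; empty neurons inherit the nearest labeled neuron on the grid.
* **Degenerate inputs.** Constant signals are rejected where a statistic is
  undefined (normalization, spectral entropy, moments) and given their
  limit value where one exists (template entropies 0, Katz FD 1). An
  infinite sample entropy (no template matches) is capped at the log of the
  template-pair count when assembling feature matrices, with a warning. An
  all-zero segment renders as a uniform spectrogram instead of NaNs.
* **RR estimation stand-in.** The published FHR estimator used alongside
  the original study is out of scope; `estimate_frri()` is a documented
  squared-energy peak picker (50 ms smoothing, 250 ms refractory, adaptive
  threshold) that recovers configured synthetic rates within 5 %. The FHR
  error tables are therefore reported in the estimator's native units
  (RR intervals in samples; AAE in beats/min).
* **Reference RR intervals** on synthetic data come from the generator's
  ground-truth beat times, not from a second estimator.

## Scales used by the test suite

The reference image size is 128×128; the identical layer stack runs at any
multiple of 32. The package's tests fit the full pipeline on 271 segments
per class with 32×32 spectrograms and short AE training (the SOM consumes
the time-series features, which carry most of the class signal), and run the
dedicated reconstruction-error separation checks at 64×64 with 100 training
spectrograms and 6 epochs, where the trained-on-high-quality separation is
comfortably established. The acceptance script runs the full pipeline at
64×64.

## Known limitations

* The generator's quality classes are far better separated than clinical
  annotations; synthetic classification metrics are upper bounds.
* The maternal-ECG cancellation step that precedes quality assessment in a
  real deployment is out of scope; the generator's default output emulates
  already-extracted FECG.
* Only the bubble neighborhood and rectangular grids are implemented for the
  SOM.
* FHR interpolation over removed segments is not implemented; removal
  reduces coverage, and the removal rate is reported so users can judge the
  trade-off.
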