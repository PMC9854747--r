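# Plain-text I/O: recordings as two-column delimited text, segment sets as a
# directory plus CSV manifest, feature matrices as CSV, spectrograms as PNG,
# SOM models as JSON.

#' Write a recording as two-column delimited text
#'
#' Columns `time_s` and `amplitude`, tab-separated, with the sampling
#' frequency recorded in a `# fs_hz:` comment header.
#'
#' @param recording `fecg_recording`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_recording <- function(recording, path) {
  fs <- recording$sampling_frequency
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs_hz: %g", fs), con)
  utils::write.table(
    data.frame(time_s = (seq_along(recording$samples) - 1) / fs,
               amplitude = recording$samples),
    con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a recording from delimited text
#'
#' Accepts the format of [write_recording()]: optional `# fs_hz:` header,
#' then `time_s` and `amplitude` columns (tab, comma or whitespace
#' separated). Without a header the sampling frequency is inferred from the
#' time column.
#'
#' @param path input file.
#' @param fs sampling frequency override in Hz.
#' @return `fecg_recording` (without ground-truth components).
#' @export
read_recording <- function(path, fs = NULL) {
  first <- readLines(path, n = 1)
  if (is.null(fs) && grepl("^#\\s*fs_hz:", first)) {
    fs <- as.numeric(sub("^#\\s*fs_hz:\\s*", "", first))
  }
  df <- utils::read.table(path, header = TRUE, comment.char = "#")
  if (is.null(fs)) {
    dt <- stats::median(diff(df[[1]]))
    if (!is.finite(dt) || dt <= 0) stopf("cannot infer sampling frequency")
    fs <- 1 / dt
  }
  structure(list(
    samples = as.numeric(df[[2]]),
    sampling_frequency = fs,
    channel_id = "file",
    subject_id = basename(path),
    fetal_beat_times = NULL,
    maternal_beat_times = NULL,
    components = NULL,
    config = NULL
  ), class = "fecg_recording")
}

#' Write a segment set as per-segment files plus a CSV manifest
#'
#' @param segments list of `fecg_segment` objects.
#' @param dir output directory (created if missing).
#' @param labels optional quality labels for the manifest.
#' @return path of the manifest CSV, invisibly.
#' @export
write_segments <- function(segments, dir, labels = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(segments), function(i) {
    s <- segments[[i]]
    id <- if (is.null(s$id)) sprintf("segment%04d", i) else s$id
    f <- file.path(dir, paste0(id, ".tsv"))
    utils::write.table(
      data.frame(time_s = s$start_time +
                   (seq_along(s$samples) - 1) / s$sampling_frequency,
                 amplitude = s$samples),
      f, sep = "\t", row.names = FALSE, quote = FALSE)
    data.frame(segment_id = id, file = basename(f), start_s = s$start_time,
               label = if (is.null(labels)) NA_character_ else
                 as.character(labels[[i]]),
               stringsAsFactors = FALSE)
  })
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(do.call(rbind, rows), manifest, row.names = FALSE)
  invisible(manifest)
}

#' Write a spectrogram image as a lossless PNG with a JSON sidecar
#'
#' @param spectrogram `fecg_spectrogram`.
#' @param path output `.png` path; the sidecar with the frequency and time
#'   ranges is written next to it with extension `.json`.
#' @return the path, invisibly.
#' @export
write_spectrogram_png <- function(spectrogram, path) {
  png::writePNG(spectrogram$pixels, path)
  jsonlite::write_json(
    list(frequency_range_hz = spectrogram$frequency_range,
         time_range_s = spectrogram$time_range),
    sub("\\.png$", ".json", path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a feature matrix as CSV
#'
#' @param X feature matrix from [extract_feature_matrix()].
#' @param path output CSV path.
#' @param labels optional quality labels appended as a `label` column.
#' @return the path, invisibly.
#' @export
write_feature_matrix <- function(X, path, labels = NULL) {
  df <- data.frame(segment_id = rownames(X), X, row.names = NULL,
                   check.names = FALSE)
  if (!is.null(labels)) df$label <- as.character(labels)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Serialize a labeled SOM model to JSON
#'
#' Stores the weights, grid, standardization statistics and neuron labels so
#' a classifier can be reloaded without retraining.
#'
#' @param model `fecg_som`.
#' @param path output `.json` path.
#' @return the path, invisibly.
#' @export
write_som_json <- function(model, path) {
  jsonlite::write_json(list(
    grid = model$grid,
    weights = model$weights,
    center = model$center,
    scale = model$scale,
    feature_names = model$feature_names,
    neuron_labels = if (is.null(model$neuron_labels)) NULL else
      as.character(model$neuron_labels)
  ), path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' Load a SOM model written by [write_som_json()]
#'
#' @param path input `.json` path.
#' @return `fecg_som`.
#' @export
read_som_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- som_model(j$weights, j$grid, center = j$center, scale = j$scale)
  model$feature_names <- j$feature_names
  if (!is.null(j$neuron_labels)) {
    model$neuron_labels <- quality_levels(j$neuron_labels)
  }
  model
}
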