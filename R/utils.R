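#' @useDynLib fecgsqa, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Quality levels are ordinal: HIGH > MEDIUM > LOW.
quality_level_names <- c("HIGH", "MEDIUM", "LOW")

#' Quality-level factor
#'
#' Coerce a character or factor vector to the three-level quality factor used
#' throughout the package (levels `HIGH`, `MEDIUM`, `LOW`, in decreasing
#' quality order).
#'
#' @param x character or factor vector of quality labels.
#' @return factor with levels `HIGH`, `MEDIUM`, `LOW`.
#' @export
quality_levels <- function(x) {
  x <- as.character(x)
  bad <- setdiff(unique(x), quality_level_names)
  if (length(bad) > 0) {
    stop("unknown quality level(s): ", paste(bad, collapse = ", "))
  }
  factor(x, levels = quality_level_names)
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_number <- function(value, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(value) || length(value) != 1 || !is.finite(value)) {
    stopf("'%s' must be a single finite number", name)
  }
  if (strict_lower && value <= lower) stopf("'%s' must be > %g", name, lower)
  if (!strict_lower && value < lower) stopf("'%s' must be >= %g", name, lower)
  if (strict_upper && value >= upper) stopf("'%s' must be < %g", name, upper)
  if (!strict_upper && value > upper) stopf("'%s' must be <= %g", name, upper)
  invisible(value)
}

as_samples <- function(x) {
  if (inherits(x, "fecg_recording") || inherits(x, "fecg_segment")) {
    return(x$samples)
  }
  if (is.numeric(x)) return(as.numeric(x))
  stop("expected a numeric vector, fecg_recording or fecg_segment")
}
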