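# Collapse per-sample connectivity matrices to the global average-strength
# (aS) time series and summarise it by its first- to fourth-order
# cumulant-based descriptors (mean, SD, skewness, kurtosis).

#' Node strength of one connectivity matrix
#'
#' Strength of node i = mean connectivity of i to every other node (the
#' diagonal is excluded). Using the mean rather than the sum keeps the value
#' scale-free in the channel count.
#'
#' @param mat Symmetric channels x channels matrix; diagonal ignored.
#' @return Numeric vector of per-node strengths.
#' @export
nodeStrength <- function(mat) {
  n <- nrow(mat)
  if (is.null(n) || n < 2L || ncol(mat) != n) {
    stop("a square matrix with at least 2 nodes is required", call. = FALSE)
  }
  diag(mat) <- 0
  rowSums(mat, na.rm = TRUE) / (n - 1)
}

#' Global average-strength time series of an IAC tensor
#'
#' aS(t) is the mean node strength at sample t, equivalently the mean over
#' all off-diagonal (upper-triangle) entries of the adjacency matrix at t:
#' one scalar per retained sample.
#'
#' @param tensor An `iac_tensor` from [iacFromBand()] or [computeIac()].
#' @return An `as_series`: `values`, `band`, `subject_id`.
#' @export
averageStrengthSeries <- function(tensor) {
  stopifnot(inherits(tensor, "iac_tensor"))
  new_as_series(colMeans(tensor$values), tensor$band, tensor$subject_id)
}

new_as_series <- function(values, band = NA_character_,
                          subject_id = NA_character_) {
  if (!all(is.finite(values))) stop("aS series contains non-finite values", call. = FALSE)
  structure(list(values = as.numeric(values), band = band,
                 subject_id = subject_id),
            class = "as_series")
}

#' @export
print.as_series <- function(x, ...) {
  cat(sprintf("<as_series> %s/%s: %d samples, mean %.4f\n",
              x$subject_id, x$band, length(x$values), mean(x$values)))
  invisible(x)
}

#' Average-strength series straight from one band-limited signal matrix
#'
#' Compiled fast path for the chain analytic signal -> (optional)
#' bidirectional orthogonalization -> envelope standardization -> per-sample
#' IAC -> global average strength, without materialising the pairs x samples
#' tensor. Numerically identical (to ~1e-12) to
#' `averageStrengthSeries(iacFromBand(...))`, which remains available as the
#' plain-R reference via `engine = "r"`.
#'
#' @param band_signal Band-limited channels x samples matrix.
#' @param orthogonalize Suppress zero-lag leakage first? Default `TRUE`.
#' @param trim Edge samples dropped at each end before standardization.
#' @param band,subject_id Metadata recorded in the series.
#' @param engine `"cpp"` (default) or `"r"` (reference path).
#' @return An `as_series`.
#' @export
asSeriesFromBand <- function(band_signal, orthogonalize = TRUE, trim = 0,
                             band = NA_character_, subject_id = NA_character_,
                             engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  if (engine == "r") {
    tens <- iacFromBand(band_signal, orthogonalize = orthogonalize, trim = trim,
                        band = band, subject_id = subject_id)
    return(averageStrengthSeries(tens))
  }
  a <- analyticSignal(band_signal)
  ntot <- ncol(a)
  trim <- as.integer(trim)
  if (trim < 0 || 2 * trim >= ntot) stop("trim must satisfy 0 <= trim < samples/2", call. = FALSE)
  keep <- (trim + 1):(ntot - trim)
  a <- a[, keep, drop = FALSE]
  vals <- cpp_as_series(Re(a), Im(a), orthogonalize)
  new_as_series(vals, band, subject_id)
}

#' Cumulant-based descriptors of an aS series
#'
#' First- to fourth-order summary of the average-strength distribution over
#' time: mean (mu), standard deviation (sigma), skewness (phi) and kurtosis
#' (kappa). Plain population (n-denominator) standardized moments are used.
#' Kurtosis is reported in the Pearson convention (Gaussian = 3); the excess
#' value (Gaussian = 0) is stored alongside as `kappa_excess`. For a
#' zero-variance series, `phi` and `kappa` are returned as `NA` with a
#' warning rather than silently zero.
#'
#' @param series An `as_series`, or a bare numeric vector (length >= 4).
#' @return A `cumulant_vector`: one-row data frame with `subject_id`, `band`,
#'   `mu`, `sigma`, `phi`, `kappa`, `kappa_excess`.
#' @export
cumulants <- function(series) {
  if (inherits(series, "as_series")) {
    x <- series$values
    band <- series$band
    sid <- series$subject_id
  } else {
    x <- as.numeric(series)
    band <- NA_character_
    sid <- NA_character_
  }
  if (length(x) < 4L) stop("at least 4 samples are required", call. = FALSE)
  mu <- mean(x)
  d <- x - mu
  m2 <- mean(d^2)
  sigma <- sqrt(m2)
  if (m2 == 0) {
    warning("zero-variance series: skewness and kurtosis are undefined")
    phi <- NA_real_
    kappa <- NA_real_
  } else {
    phi <- mean(d^3) / m2^1.5
    kappa <- mean(d^4) / m2^2
  }
  out <- data.frame(subject_id = sid, band = band, mu = mu, sigma = sigma,
                    phi = phi, kappa = kappa, kappa_excess = kappa - 3,
                    stringsAsFactors = FALSE)
  class(out) <- c("cumulant_vector", "data.frame")
  out
}

#' Per-band cumulant table for one recording
#'
#' Runs the full single-subject chain: broadband + notch preprocessing,
#' canonical band decomposition, orthogonalized IAC average strength per
#' band, and the four cumulant-based descriptors. Rows = bands.
#'
#' @param rec An [eegRecording()].
#' @param bands Band table (default [canonicalBands()]).
#' @param order FIR order for all filters.
#' @param orthogonalize Leakage correction on/off.
#' @param trim Edge samples dropped per end before envelope statistics.
#' @param preprocess Apply the broadband band-pass + notch first? Default
#'   `TRUE`.
#' @param engine aS computation engine, `"cpp"` or `"r"`.
#' @return Data frame: `subject_id`, `group`, `band`, `mu`, `sigma`, `phi`,
#'   `kappa`, `kappa_excess` (+ one column per covariate).
#' @export
subjectCumulants <- function(rec, bands = canonicalBands(rec$fs), order = 500,
                             orthogonalize = TRUE, trim = 0,
                             preprocess = TRUE, engine = "cpp") {
  stopifnot(inherits(rec, "eeg_recording"))
  if (preprocess) rec <- preprocessRecording(rec, order = order)
  bset <- bandDecompose(rec, bands = bands, order = order)
  rows <- lapply(names(bset$bands), function(bn) {
    s <- asSeriesFromBand(bset$bands[[bn]], orthogonalize = orthogonalize,
                          trim = trim, band = bn, subject_id = rec$subject_id,
                          engine = engine)
    cumulants(s)
  })
  out <- do.call(rbind, rows)
  out$group <- rec$group
  if (!is.null(rec$covariates)) {
    for (nm in names(rec$covariates)) out[[nm]] <- rec$covariates[[nm]]
  }
  rownames(out) <- NULL
  out[, c("subject_id", "group", setdiff(names(out), c("subject_id", "group")))]
}

#' Cumulant table for a whole cohort
#'
#' @param recordings List of [eegRecording()] objects (e.g. from
#'   [generateCohort()]).
#' @param ... Passed to [subjectCumulants()].
#' @return Long data frame, one row per subject x band.
#' @export
cohortCumulants <- function(recordings, ...) {
  tabs <- lapply(recordings, subjectCumulants, ...)
  # covariates may exist for only some subjects: pad the rest with NA so
  # the per-subject tables bind into one rectangular frame
  all_cols <- unique(unlist(lapply(tabs, names)))
  tabs <- lapply(tabs, function(tb) {
    for (cn in setdiff(all_cols, names(tb))) tb[[cn]] <- NA_real_
    tb[, all_cols, drop = FALSE]
  })
  out <- do.call(rbind, tabs)
  rownames(out) <- NULL
  out
}
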