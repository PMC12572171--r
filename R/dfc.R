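# Core dynamic-connectivity metric: per-sample instantaneous amplitude
# correlation (IAC) from leakage-corrected, normalized Hilbert envelopes.
#
# For each channel pair (i, j) and sample t,
#     IAC_ij(t) = E^_i(t) * E^_j(t),
# where E^ is the envelope standardized to time-mean 0 and variance 1.
# Standardizing with the population (n-denominator) variance makes the time
# average of IAC_ij exactly the Pearson correlation of the two envelopes, so
# the static amplitude-envelope correlation is recovered as the time-mean of
# the dynamic metric.
#
# Volume-conduction leakage is suppressed by pairwise time-resolved
# orthogonalization of the analytic signals: the component of one signal
# collinear (zero phase lag) with the other is removed per sample before the
# envelope is taken. Orthogonalization is directional, so both directions are
# computed and the two per-sample products averaged, preserving symmetry.

#' Analytic signal via the Hilbert transform
#'
#' FFT construction of the analytic signal (positive frequencies doubled,
#' negative zeroed), applied per channel.
#'
#' @param x Numeric vector or channels x samples matrix (band-limited).
#' @return Complex vector/matrix of the same shape.
#' @export
analyticSignal <- function(x) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, nrow = 1)
  n <- ncol(x)
  h <- rep(0, n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  X <- stats::mvfft(t(x)) * h
  a <- t(stats::mvfft(X, inverse = TRUE)) / n
  dimnames(a) <- dimnames(x)
  if (vec) a[1, ] else a
}

#' Amplitude envelope of a band-limited signal
#'
#' Modulus of the analytic signal per channel; nonnegative, and invariant to
#' a phase shift of the carrier.
#'
#' @param x Numeric vector or channels x samples matrix (band-limited).
#' @return Nonnegative envelope of the same shape.
#' @export
analyticEnvelope <- function(x) {
  env <- Mod(analyticSignal(x))
  if (is.matrix(env)) {
    v <- apply(env, 1, stats::var)
    if (any(v == 0)) stop("constant (zero-variance) channel", call. = FALSE)
  } else if (stats::var(env) == 0 && stats::var(x) == 0) {
    stop("constant (zero-variance) channel", call. = FALSE)
  }
  env
}

# Magnitude floor used when dividing by |x(t)| during orthogonalization.
orth_floor <- function(mag) 1e-12 * stats::median(mag)

#' Orthogonalize one analytic signal against another
#'
#' Time-resolved leakage correction: removes, at every sample, the component
#' of `y` collinear (zero phase lag) with `x`, returning the signed residual
#' amplitude `Im(y(t) * Conj(x(t)) / |x(t)|)`. Its absolute value is the
#' envelope of y orthogonalized to x; for `y` proportional to `x` it vanishes
#' identically.
#'
#' @param x_analytic,y_analytic Complex analytic signals of equal length and
#'   band.
#' @return Numeric vector: signed orthogonalized amplitude of `y` w.r.t. `x`.
#' @export
orthogonalizePair <- function(x_analytic, y_analytic) {
  if (length(x_analytic) != length(y_analytic)) {
    stop("analytic signals must have equal length", call. = FALSE)
  }
  mag <- Mod(x_analytic)
  Im(y_analytic * Conj(x_analytic)) / pmax(mag, orth_floor(mag))
}

#' Standardize envelopes over the retained span
#'
#' Trims `trim` samples from each end (zero-phase FIR transients) and
#' z-scores each channel's envelope with the population (n-denominator)
#' standard deviation, so each retained envelope has time-mean 0 and variance
#' 1 and time-averaged envelope products are exact Pearson correlations.
#'
#' @param envelope Nonnegative channels x samples matrix.
#' @param trim Edge samples to drop at each end (< samples / 2).
#' @return An `envelope_set`: `env` (channels x retained samples), `trim`.
#' @export
normalizeEnvelope <- function(envelope, trim = 0) {
  if (is.null(dim(envelope))) envelope <- matrix(envelope, nrow = 1)
  n <- ncol(envelope)
  trim <- as.integer(trim)
  if (trim < 0 || 2 * trim >= n) stop("trim must satisfy 0 <= trim < samples/2", call. = FALSE)
  keep <- (trim + 1):(n - trim)
  env <- envelope[, keep, drop = FALSE]
  env <- t(apply(env, 1, zscore_pop, label = "envelope"))
  structure(list(env = env, trim = trim, retained = length(keep)),
            class = "envelope_set")
}

# Upper-triangle pair index for n channels: 2 x P matrix of (i, j), i < j.
pair_index <- function(n) {
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  t(unname(idx))
}

#' Per-sample instantaneous amplitude correlation from normalized envelopes
#'
#' The element-wise (Hadamard) product of standardized envelopes for every
#' channel pair: one symmetric adjacency matrix per retained sample, stored
#' compactly as upper-triangle pairs x samples.
#'
#' @param envelopes An [normalizeEnvelope()] `envelope_set`.
#' @param band Band name recorded in the result.
#' @param subject_id Subject identifier recorded in the result.
#' @param channel_labels Optional channel names.
#' @return An `iac_tensor`: `values` (pairs x samples), `pairs` (2 x P index),
#'   `band`, `subject_id`, `n_channels`, `trim`.
#' @export
computeIac <- function(envelopes, band = NA_character_, subject_id = NA_character_,
                       channel_labels = NULL) {
  stopifnot(inherits(envelopes, "envelope_set"))
  E <- envelopes$env
  n <- nrow(E)
  if (n < 2L) stop("at least 2 channels are required", call. = FALSE)
  pairs <- pair_index(n)
  values <- E[pairs[1, ], , drop = FALSE] * E[pairs[2, ], , drop = FALSE]
  new_iac_tensor(values, pairs, n, envelopes$trim, band, subject_id,
                 channel_labels, orthogonalized = FALSE)
}

new_iac_tensor <- function(values, pairs, n_channels, trim, band, subject_id,
                           channel_labels, orthogonalized) {
  structure(
    list(values = values, pairs = pairs, n_channels = n_channels,
         trim = trim, band = band, subject_id = subject_id,
         channel_labels = channel_labels, orthogonalized = orthogonalized),
    class = "iac_tensor"
  )
}

#' @export
print.iac_tensor <- function(x, ...) {
  cat(sprintf("<iac_tensor> %s/%s: %d channels (%d pairs) x %d samples%s\n",
              x$subject_id, x$band, x$n_channels, nrow(x$values),
              ncol(x$values),
              if (x$orthogonalized) ", orthogonalized" else ""))
  invisible(x)
}

#' Reconstruct the full adjacency matrix at one sample
#'
#' @param tensor An `iac_tensor`.
#' @param t Sample index (1-based, within the retained span).
#' @return Symmetric channels x channels matrix; the diagonal is `NA`
#'   (self-connectivity is excluded from every downstream statistic).
#' @export
iacMatrixAt <- function(tensor, t) {
  stopifnot(inherits(tensor, "iac_tensor"))
  n <- tensor$n_channels
  M <- matrix(NA_real_, n, n)
  v <- tensor$values[, t]
  M[cbind(tensor$pairs[1, ], tensor$pairs[2, ])] <- v
  M[cbind(tensor$pairs[2, ], tensor$pairs[1, ])] <- v
  if (!is.null(tensor$channel_labels)) {
    dimnames(M) <- list(tensor$channel_labels, tensor$channel_labels)
  }
  M
}

#' IAC tensor from one band-limited signal matrix
#'
#' Full core computation for one band of one recording: analytic signal,
#' optional pairwise bidirectional orthogonalization, envelope
#' standardization over the retained span, and the per-sample envelope
#' product. With `orthogonalize = TRUE` each pair value is the average of the
#' two directional products
#' `0.5 * (E^_{i|j}(t) E^_j(t) + E^_{j|i}(t) E^_i(t))`,
#' which keeps the tensor exactly symmetric.
#'
#' This is the plain-R reference path; [asSeriesFromBand()] provides an
#' equivalent compiled fast path when only the global average strength is
#' needed.
#'
#' @param band_signal Band-limited channels x samples matrix.
#' @param orthogonalize Suppress zero-lag leakage first? Default `TRUE`.
#' @param trim Edge samples dropped at each end before standardization
#'   (default 0, which reproduces the full per-sample count).
#' @param band,subject_id,channel_labels Metadata recorded in the tensor.
#' @return An `iac_tensor`.
#' @export
iacFromBand <- function(band_signal, orthogonalize = TRUE, trim = 0,
                        band = NA_character_, subject_id = NA_character_,
                        channel_labels = rownames(band_signal)) {
  a <- analyticSignal(band_signal)
  n <- nrow(a)
  if (n < 2L) stop("at least 2 channels are required", call. = FALSE)
  ntot <- ncol(a)
  trim <- as.integer(trim)
  if (trim < 0 || 2 * trim >= ntot) stop("trim must satisfy 0 <= trim < samples/2", call. = FALSE)
  keep <- (trim + 1):(ntot - trim)
  if (!orthogonalize) {
    es <- normalizeEnvelope(Mod(a), trim = trim)
    tens <- computeIac(es, band = band, subject_id = subject_id,
                       channel_labels = channel_labels)
    return(tens)
  }
  E <- Mod(a)[, keep, drop = FALSE]
  Ez <- t(apply(E, 1, zscore_pop, label = "envelope"))
  pairs <- pair_index(n)
  values <- matrix(0, ncol(pairs), length(keep))
  # A collinear pair leaves a zero-variance orthogonalized envelope (nothing
  # survives leakage removal); its standardized series is taken as 0, so the
  # pair contributes no connectivity rather than erroring out.
  zsafe <- function(x) {
    m <- mean(x); s <- sqrt(mean((x - m)^2))
    if (s <= 1e-14 * max(abs(m), 1)) rep(0, length(x)) else (x - m) / s
  }
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1, p]; j <- pairs[2, p]
    e_ij <- abs(orthogonalizePair(a[j, ], a[i, ]))[keep]   # i orthogonalized to j
    e_ji <- abs(orthogonalizePair(a[i, ], a[j, ]))[keep]   # j orthogonalized to i
    values[p, ] <- 0.5 * (zsafe(e_ij) * Ez[j, ] + zsafe(e_ji) * Ez[i, ])
  }
  new_iac_tensor(values, pairs, n, trim, band, subject_id, channel_labels,
                 orthogonalized = TRUE)
}
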