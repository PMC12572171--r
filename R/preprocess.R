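# Deterministic preprocessing: Hamming-window FIR band-pass, 50 Hz notch,
# fixed-length segment selection and decomposition into the canonical bands.
# All filtering is zero-phase (forward-backward), so per-sample connectivity
# is never phase-shifted between channels.

#' Design a linear-phase FIR filter
#'
#' Hamming-window FIR design (via [signal::fir1]); `kind = "bandpass"` passes
#' `[f_lo, f_hi]`, `kind = "notch"` is a band-stop over the same interval.
#'
#' @param f_lo,f_hi Band edges in Hz, inside (0, Nyquist).
#' @param order Filter order (>= 2); the coefficient vector has `order + 1`
#'   taps. Default 500.
#' @param fs Sampling rate in Hz.
#' @param kind `"bandpass"` or `"notch"` (band-stop).
#' @return A `fir_filter` list: `coef`, `order`, `fs`, `kind`, `f_lo`, `f_hi`.
#' @export
designFir <- function(f_lo, f_hi, order = 500, fs = 500,
                      kind = c("bandpass", "notch")) {
  kind <- match.arg(kind)
  stopifnot_scalar(order, "order", lo = 2)
  stopifnot_scalar(fs, "fs", lo = 1)
  nyq <- fs / 2
  if (!(f_lo > 0 && f_hi > f_lo && f_hi < nyq)) {
    stop("band edges must satisfy 0 < f_lo < f_hi < Nyquist", call. = FALSE)
  }
  type <- if (kind == "bandpass") "pass" else "stop"
  coef <- signal::fir1(order, c(f_lo, f_hi) / nyq, type = type,
                       window = signal::hamming(order + 1))
  structure(list(coef = as.numeric(coef), order = as.integer(order), fs = fs,
                 kind = kind, f_lo = f_lo, f_hi = f_hi),
            class = "fir_filter")
}

#' Magnitude response of an FIR filter
#'
#' @param filt A [designFir()] filter.
#' @param freqs Frequencies (Hz) at which to evaluate.
#' @return Linear-scale magnitude at each frequency (single-pass response).
#' @export
firResponse <- function(filt, freqs) {
  k <- seq_along(filt$coef) - 1
  vapply(freqs, function(f) {
    Mod(sum(filt$coef * exp(-2i * pi * f * k / filt$fs)))
  }, numeric(1))
}

# Zero-phase FIR application via FFT convolution with the forward-backward
# kernel conv(h, rev(h)) and odd edge-reflection padding (classic filtfilt
# padding). Operates on a channels x samples matrix in one multivariate FFT
# pass; returns the same shape.
filtfilt_fft <- function(x, coef) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, nrow = 1)
  n <- ncol(x)
  L <- length(coef) - 1L                   # filter order; kernel delay is L
  g <- Re(stats::convolve(coef, rev(coef), type = "open"))
  pad <- min(L, n - 1L)
  left <- 2 * x[, 1] - x[, (pad + 1):2, drop = FALSE]
  right <- 2 * x[, n] - x[, (n - 1):(n - pad), drop = FALSE]
  xp <- cbind(left, x, right)
  m <- ncol(xp) + length(g) - 1L
  nfft <- stats::nextn(m, 2)
  XP <- matrix(0, nfft, nrow(x))
  XP[seq_len(ncol(xp)), ] <- t(xp)
  G <- stats::fft(c(g, rep(0, nfft - length(g))))
  Y <- stats::mvfft(stats::mvfft(XP) * G, inverse = TRUE)
  y <- t(Re(Y[(pad + L + 1):(pad + L + n), , drop = FALSE])) / nfft
  dimnames(y) <- dimnames(x)
  if (vec) y[1, ] else y
}

#' Apply an FIR filter with zero phase
#'
#' Forward-backward application per channel (squared magnitude response, zero
#' phase lag), so the output shape equals the input shape and narrowband
#' components are not delayed.
#'
#' @param x An [eegRecording()] or a channels x samples numeric matrix.
#' @param filt A [designFir()] filter designed for the recording's sampling
#'   rate.
#' @param fs Sampling rate, required when `x` is a bare matrix.
#' @return Same type as `x`, filtered.
#' @export
applyFir <- function(x, filt, fs = NULL) {
  stopifnot(inherits(filt, "fir_filter"))
  if (inherits(x, "eeg_recording")) {
    if (!isTRUE(all.equal(x$fs, filt$fs))) {
      stop("filter was designed for fs = ", filt$fs,
           " but the recording has fs = ", x$fs, call. = FALSE)
    }
    out <- x
    out$data <- applyFir(x$data, filt, fs = x$fs)
    return(out)
  }
  if (!is.null(fs) && !isTRUE(all.equal(fs, filt$fs))) {
    stop("filter fs does not match the data fs", call. = FALSE)
  }
  filtfilt_fft(x, filt$coef)
}

#' Select a contiguous segment of a recording
#'
#' @param rec An [eegRecording()].
#' @param start Segment start in seconds (0 = first sample).
#' @param duration Segment length in seconds; `duration * fs` samples are
#'   returned and the segment must fit inside the recording.
#' @return An [eegRecording()] holding the slice.
#' @export
selectSegment <- function(rec, start, duration) {
  stopifnot(inherits(rec, "eeg_recording"))
  stopifnot_scalar(start, "start", lo = 0)
  stopifnot_scalar(duration, "duration", lo = .Machine$double.eps)
  i0 <- round(start * rec$fs) + 1
  n <- round(duration * rec$fs)
  if (i0 + n - 1 > ncol(rec$data)) {
    stop("requested segment extends beyond the recording", call. = FALSE)
  }
  out <- rec
  out$data <- rec$data[, i0:(i0 + n - 1), drop = FALSE]
  out
}

#' Broadband preprocessing: band-pass plus power-line notch
#'
#' Zero-phase FIR band-pass (default 0.5-98 Hz, order 500, Hamming) followed
#' by a zero-phase FIR band-stop notch (default 48-52 Hz, order 500, Hamming)
#' against 50 Hz mains interference.
#'
#' @param rec An [eegRecording()].
#' @param bp_lo,bp_hi Broadband pass edges in Hz.
#' @param notch_lo,notch_hi Notch stop-band edges in Hz; `NULL` disables the
#'   notch (e.g. when fs is too low).
#' @param order FIR order for both filters.
#' @return The filtered [eegRecording()].
#' @export
preprocessRecording <- function(rec, bp_lo = 0.5, bp_hi = 98,
                                notch_lo = 48, notch_hi = 52, order = 500) {
  stopifnot(inherits(rec, "eeg_recording"))
  bp_hi <- min(bp_hi, 0.49 * rec$fs)
  out <- applyFir(rec, designFir(bp_lo, bp_hi, order, rec$fs, "bandpass"))
  if (!is.null(notch_lo) && notch_hi < rec$fs / 2) {
    out <- applyFir(out, designFir(notch_lo, notch_hi, order, rec$fs, "notch"))
  }
  out
}

#' Decompose a recording into canonical frequency bands
#'
#' One zero-phase band-filtered copy per band, same shape as the input.
#'
#' @param rec An [eegRecording()] (typically already broadband-filtered).
#' @param bands Data frame `name`, `f_lo`, `f_hi` as from [canonicalBands()].
#' @param order FIR order (default 500).
#' @return An `eeg_band_set`: named list of channels x samples matrices plus
#'   `fs`, `channel_labels`, metadata and the filter parameters used.
#' @export
bandDecompose <- function(rec, bands = canonicalBands(rec$fs), order = 500) {
  stopifnot(inherits(rec, "eeg_recording"))
  nyq <- rec$fs / 2
  mats <- vector("list", nrow(bands))
  names(mats) <- bands$name
  for (b in seq_len(nrow(bands))) {
    f_hi <- min(bands$f_hi[b], 0.49 * rec$fs)
    filt <- designFir(bands$f_lo[b], f_hi, order, rec$fs, "bandpass")
    mats[[b]] <- applyFir(rec$data, filt, fs = rec$fs)
  }
  structure(list(bands = mats, band_table = bands, fs = rec$fs,
                 channel_labels = rec$channel_labels,
                 subject_id = rec$subject_id, group = rec$group,
                 covariates = rec$covariates,
                 filter = list(order = order, window = "hamming")),
            class = "eeg_band_set")
}

#' @export
print.eeg_band_set <- function(x, ...) {
  cat(sprintf("<eeg_band_set> %s: %d bands (%s), %d channels x %d samples @ %g Hz\n",
              x$subject_id, length(x$bands),
              paste(names(x$bands), collapse = ", "),
              nrow(x$bands[[1]]), ncol(x$bands[[1]]), x$fs))
  invisible(x)
}
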