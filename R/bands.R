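#' Canonical EEG frequency bands
#'
#' Returns the five classical frequency bands used throughout the package:
#' delta (0.5-4 Hz), theta (4-8 Hz), alpha (8-13 Hz), beta (13-30 Hz) and
#' gamma (above 30 Hz). The gamma upper edge is capped at 98 Hz, the upper
#' limit of the broadband anti-noise filter, and never exceeds 96% of the
#' Nyquist frequency.
#'
#' @param fs Sampling rate in Hz, used only to cap the gamma band below
#'   Nyquist. Default 500.
#' @return A data frame with columns `name`, `f_lo`, `f_hi` (Hz).
#' @export
#' @examples
#' canonicalBands()
canonicalBands <- function(fs = 500) {
  stopifnot_scalar(fs, "fs", lo = 1)
  gamma_hi <- min(98, 0.48 * fs)
  if (gamma_hi <= 30) stop("sampling rate too low for a gamma band", call. = FALSE)
  data.frame(
    name = c("delta", "theta", "alpha", "beta", "gamma"),
    f_lo = c(0.5, 4, 8, 13, 30),
    f_hi = c(4, 8, 13, 30, gamma_hi),
    stringsAsFactors = FALSE
  )
}

#' Validate a band definition
#'
#' Checks that a named frequency interval is usable at a given sampling rate:
#' positive lower edge, increasing edges, upper edge at or below Nyquist.
#'
#' @param name Band name (string).
#' @param f_lo,f_hi Band edges in Hz.
#' @param fs Sampling rate in Hz.
#' @return A one-row data frame `name`, `f_lo`, `f_hi`, invisibly validated.
#' @export
bandDefinition <- function(name, f_lo, f_hi, fs) {
  stopifnot(is.character(name), length(name) == 1L)
  stopifnot_scalar(f_lo, "f_lo", lo = .Machine$double.eps)
  stopifnot_scalar(f_hi, "f_hi")
  stopifnot_scalar(fs, "fs", lo = 1)
  if (!(f_lo < f_hi)) stop("f_lo must be below f_hi", call. = FALSE)
  if (f_hi > fs / 2) stop("f_hi exceeds the Nyquist frequency", call. = FALSE)
  data.frame(name = name, f_lo = f_lo, f_hi = f_hi, stringsAsFactors = FALSE)
}
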