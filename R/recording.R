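#' Construct an EEG recording object
#'
#' The central data container: a channels-by-samples numeric matrix with its
#' sampling rate, channel labels and subject metadata.
#'
#' @param data Numeric matrix, channels in rows, samples in columns.
#' @param fs Sampling rate in Hz.
#' @param channel_labels Character vector of unique channel names; defaults
#'   to `Ch01`, `Ch02`, ...
#' @param subject_id Subject identifier.
#' @param group Group label (e.g. `"HC"`, `"SCZ"`), or `NA`.
#' @param covariates Named numeric vector of per-subject covariates (e.g. a
#'   chlorpromazine-equivalent dose), or `NULL`.
#' @return An object of class `eeg_recording`.
#' @export
eegRecording <- function(data, fs, channel_labels = NULL, subject_id = "S1",
                         group = NA_character_, covariates = NULL) {
  if (!is.matrix(data) || !is.numeric(data)) {
    stop("'data' must be a numeric matrix (channels x samples)", call. = FALSE)
  }
  if (nrow(data) < 2L) stop("at least 2 channels are required", call. = FALSE)
  if (anyNA(data)) stop("recording contains missing samples", call. = FALSE)
  stopifnot_scalar(fs, "fs", lo = .Machine$double.eps)
  if (is.null(channel_labels)) {
    channel_labels <- sprintf("Ch%02d", seq_len(nrow(data)))
  }
  if (length(channel_labels) != nrow(data)) {
    stop("channel_labels length must match the number of channels", call. = FALSE)
  }
  if (anyDuplicated(channel_labels)) stop("channel labels must be unique", call. = FALSE)
  if (!is.null(covariates)) {
    if (!is.numeric(covariates) || is.null(names(covariates))) {
      stop("'covariates' must be a named numeric vector", call. = FALSE)
    }
  }
  rownames(data) <- channel_labels
  structure(
    list(data = data, fs = fs, channel_labels = channel_labels,
         subject_id = subject_id, group = group, covariates = covariates),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s%s: %d channels x %d samples @ %g Hz (%.1f s)\n",
              x$subject_id,
              if (is.na(x$group)) "" else paste0(" [", x$group, "]"),
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  if (!is.null(x$covariates)) {
    cat("  covariates:", paste(names(x$covariates), signif(x$covariates, 4),
                               sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of channels / samples of a recording
#' @param x An `eeg_recording`.
#' @return Integer count.
#' @export
nChannels <- function(x) nrow(x$data)

#' @rdname nChannels
#' @export
nSamples <- function(x) ncol(x$data)
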