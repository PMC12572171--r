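# Recording I/O: 16-bit EDF (European Data Format), delimited text with a
# YAML sidecar, and cohort manifests.

pad_ascii <- function(x, width) {
  x <- as.character(x)
  x <- substr(x, 1, width)
  formatC(x, width = -width, flag = " ")
}

num_ascii <- function(x, width) {
  s <- formatC(x, format = "g", digits = 6)
  if (nchar(s) > width) s <- formatC(x, format = "g", digits = 4)
  if (nchar(s) > width) s <- formatC(x, format = "g", digits = 2)
  pad_ascii(s, width)
}

#' Write a recording as 16-bit EDF
#'
#' Standard EDF with one-second data records; the recording is truncated to
#' a whole number of seconds and `fs` must be an integer. Physical scaling
#' is symmetric per channel, so amplitudes round-trip within the 16-bit
#' quantization step.
#'
#' @param rec An [eegRecording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeEdf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9) stop("EDF export requires an integer sampling rate", call. = FALSE)
  fs <- as.integer(round(fs))
  nch <- nrow(rec$data)
  n_rec <- ncol(rec$data) %/% fs
  if (n_rec < 1L) stop("recording shorter than one data record (1 s)", call. = FALSE)
  X <- rec$data[, seq_len(n_rec * fs), drop = FALSE]

  pmax_ <- pmax(apply(abs(X), 1, max), .Machine$double.eps)
  pmax_ <- signif(pmax_ * 1.001, 6)
  dig_min <- -32768L; dig_max <- 32767L
  D <- matrix(0L, nch, ncol(X))
  for (i in seq_len(nch)) {
    # same affine map the reader inverts, so round-trip error <= half an LSB
    d <- round((X[i, ] + pmax_[i]) / (2 * pmax_[i]) * (dig_max - dig_min) + dig_min)
    D[i, ] <- as.integer(pmin(pmax(d, dig_min), dig_max))
  }

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(s, con, nchars = nchar(s), eos = NULL)
  header_bytes <- 256L + 256L * nch
  wr(pad_ascii("0", 8))
  wr(pad_ascii(rec$subject_id, 80))
  wr(pad_ascii(paste0("Startdate 01.01.2000 group=",
                      ifelse(is.na(rec$group), "NA", rec$group)), 80))
  wr(pad_ascii("01.01.00", 8))
  wr(pad_ascii("00.00.00", 8))
  wr(pad_ascii(header_bytes, 8))
  wr(pad_ascii("", 44))
  wr(pad_ascii(n_rec, 8))
  wr(pad_ascii(1, 8))
  wr(pad_ascii(nch, 4))
  wr(paste0(vapply(rec$channel_labels, pad_ascii, "", width = 16), collapse = ""))
  wr(strrep(" ", 80 * nch))                         # transducer
  wr(paste0(rep(pad_ascii("uV", 8), nch), collapse = ""))
  wr(paste0(vapply(-pmax_, num_ascii, "", width = 8), collapse = ""))
  wr(paste0(vapply(pmax_, num_ascii, "", width = 8), collapse = ""))
  wr(paste0(rep(pad_ascii(dig_min, 8), nch), collapse = ""))
  wr(paste0(rep(pad_ascii(dig_max, 8), nch), collapse = ""))
  wr(strrep(" ", 80 * nch))                         # prefiltering
  wr(paste0(rep(pad_ascii(fs, 8), nch), collapse = ""))
  wr(strrep(" ", 32 * nch))
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1) * fs + 1):(r * fs)
    writeBin(as.integer(t(D[, cols, drop = FALSE])), con, size = 2,
             endian = "little")
  }
  invisible(path)
}

#' Read a 16-bit EDF file
#'
#' @param path EDF file path.
#' @return An [eegRecording()]; the group label is recovered from the
#'   recording-id field when this package wrote the file.
#' @export
readEdf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) trimws(readChar(con, n, useBytes = TRUE))
  rd(8)                                   # version
  subject_id <- rd(80)
  rec_id <- rd(80)
  rd(8); rd(8)                            # date, time
  rd(8)                                   # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  nch <- as.integer(rd(4))
  labels <- vapply(seq_len(nch), function(i) rd(16), "")
  rd(80 * nch)
  rd(8 * nch)                             # physical dimension
  pmin_ <- vapply(seq_len(nch), function(i) as.numeric(rd(8)), 0)
  pmax_ <- vapply(seq_len(nch), function(i) as.numeric(rd(8)), 0)
  dmin_ <- vapply(seq_len(nch), function(i) as.numeric(rd(8)), 0)
  dmax_ <- vapply(seq_len(nch), function(i) as.numeric(rd(8)), 0)
  rd(80 * nch)
  spr <- vapply(seq_len(nch), function(i) as.integer(rd(8)), 0L)
  rd(32 * nch)
  if (length(unique(spr)) != 1L) stop("mixed sampling rates are not supported", call. = FALSE)
  fs <- spr[1] / rec_dur
  X <- matrix(0, nch, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    d <- readBin(con, "integer", n = nch * spr[1], size = 2, endian = "little")
    block <- matrix(d, nrow = spr[1], ncol = nch)
    cols <- ((r - 1) * spr[1] + 1):(r * spr[1])
    X[, cols] <- t(block)
  }
  for (i in seq_len(nch)) {
    X[i, ] <- (X[i, ] - dmin_[i]) * (pmax_[i] - pmin_[i]) /
      (dmax_[i] - dmin_[i]) + pmin_[i]
  }
  group <- NA_character_
  gm <- regmatches(rec_id, regexpr("group=\\S+", rec_id))
  if (length(gm) == 1L) group <- sub("group=", "", gm)
  if (identical(group, "NA")) group <- NA_character_
  eegRecording(X, fs = fs, channel_labels = labels, subject_id = subject_id,
               group = group)
}

sidecar_path <- function(path) paste0(path, ".meta.yaml")

#' Write a recording as delimited text plus a YAML sidecar
#'
#' Tab-separated samples x channels matrix with a header row of channel
#' labels; sampling rate and subject metadata go to `<path>.meta.yaml`.
#'
#' @param rec An [eegRecording()].
#' @param path Output data file path.
#' @return `path`, invisibly.
#' @export
writeRecordingDelim <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  df <- as.data.frame(t(rec$data))
  names(df) <- rec$channel_labels
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  meta <- list(fs = rec$fs, channel_labels = as.list(rec$channel_labels),
               subject_id = rec$subject_id,
               group = if (is.na(rec$group)) NULL else rec$group,
               covariates = if (is.null(rec$covariates)) NULL else as.list(rec$covariates))
  yaml::write_yaml(meta, sidecar_path(path))
  invisible(path)
}

#' Read a recording from EDF or delimited text
#'
#' Format is chosen by extension (`.edf` / `.EDF`) unless given explicitly.
#' Delimited files require their `<path>.meta.yaml` sidecar carrying at
#' least the sampling rate.
#'
#' @param path Input file path.
#' @param format `"auto"`, `"edf"` or `"delimited"`.
#' @return An [eegRecording()].
#' @export
readRecording <- function(path, format = c("auto", "edf", "delimited")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "delimited"
  }
  if (format == "edf") return(readEdf(path))
  sc <- sidecar_path(path)
  if (!file.exists(sc)) {
    stop("missing sidecar '", sc, "' (sampling rate unknown)", call. = FALSE)
  }
  meta <- yaml::read_yaml(sc)
  if (is.null(meta$fs)) stop("sidecar does not define 'fs'", call. = FALSE)
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  X <- t(as.matrix(df))
  labels <- unlist(meta$channel_labels) %||% colnames(df)
  if (length(labels) != nrow(X)) {
    stop("sidecar channel labels do not match the data columns", call. = FALSE)
  }
  covs <- if (!is.null(meta$covariates)) unlist(meta$covariates) else NULL
  eegRecording(X, fs = meta$fs, channel_labels = labels,
               subject_id = meta$subject_id %||% "S1",
               group = meta$group %||% NA_character_, covariates = covs)
}

#' Write / read a cohort manifest
#'
#' Tabular per-subject provenance: subject id, group, seed, covariates and
#' (optionally) the recording file path.
#'
#' @param manifest Data frame (e.g. `attr(generateCohort(...), "manifest")`).
#' @param path CSV file path.
#' @return `path` / the manifest data frame.
#' @export
writeManifest <- function(manifest, path) {
  write.table(manifest, path, sep = ",", row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname writeManifest
#' @export
readManifest <- function(path) {
  read.table(path, header = TRUE, sep = ",", stringsAsFactors = FALSE)
}
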