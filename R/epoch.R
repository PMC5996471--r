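#' EEG epoch objects
#'
#' An `eeg_epoch` is the unit of analysis: a fixed-length, single- or
#' multi-channel stretch of signal with a known sampling rate, stored in
#' microvolts. Channels are columns, samples are rows.
#'
#' @param samples Numeric vector (single channel) or matrix with one column
#'   per channel and one row per sample, in microvolts.
#' @param sampling_rate Sampling rate in Hz (positive).
#' @param channel_names Optional character vector of channel labels.
#' @param source_id Free-text provenance tag (file name, generator spec, ...).
#' @return An object of class `eeg_epoch` with fields `samples` (matrix),
#'   `sampling_rate`, `channel_names` and `source_id`.
#' @examples
#' e <- eeg_epoch(sin(seq(0, 2 * pi, length.out = 100)), sampling_rate = 100)
#' e
#' @export
eeg_epoch <- function(samples, sampling_rate, channel_names = NULL,
                      source_id = "") {
  if (is.null(dim(samples))) samples <- matrix(as.numeric(samples), ncol = 1)
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (nrow(samples) < 2) stop("an epoch needs at least 2 samples")
  if (!all(is.finite(samples))) stop("epoch contains non-finite samples")
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1 ||
      sampling_rate <= 0) stop("sampling_rate must be a positive number")
  if (!is.null(channel_names) && length(channel_names) != ncol(samples))
    stop("channel_names must match the number of channels")
  structure(
    list(samples = samples, sampling_rate = as.numeric(sampling_rate),
         channel_names = channel_names, source_id = as.character(source_id)),
    class = "eeg_epoch")
}

#' @export
print.eeg_epoch <- function(x, ...) {
  cat(sprintf("<eeg_epoch> %d samples x %d channel(s) @ %g Hz (%.3f s)\n",
              nrow(x$samples), ncol(x$samples), x$sampling_rate,
              nrow(x$samples) / x$sampling_rate))
  if (nzchar(x$source_id)) cat("  source:", x$source_id, "\n")
  invisible(x)
}

#' @export
as.matrix.eeg_epoch <- function(x, ...) x$samples

#' Number of samples per channel in an epoch
#' @param epoch An `eeg_epoch`.
#' @return Integer sample count.
#' @export
n_samples <- function(epoch) nrow(epoch$samples)

# Coerce an epoch (or bare numeric) to a single-channel numeric vector.
as_signal_vector <- function(x, channel = 1L) {
  if (inherits(x, "eeg_epoch")) {
    if (channel > ncol(x$samples)) stop("channel index out of range")
    return(as.numeric(x$samples[, channel]))
  }
  if (is.numeric(x)) return(as.numeric(x))
  stop("expected an eeg_epoch or a numeric vector")
}

#' Read an epoch from delimited ASCII text
#'
#' Files are plain numeric text, one row per sample and one column per
#' channel, separated by whitespace and/or commas. Lines starting with `#`
#' and blank lines are ignored.
#'
#' @param path Path to the text file.
#' @param sampling_rate Sampling rate of the stored signal in Hz.
#' @return An [eeg_epoch()] with `source_id` set to the file name.
#' @export
read_epoch_text <- function(path, sampling_rate) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  data_lines <- lines[keep]
  data_nums <- which(keep)
  if (length(data_lines) == 0) stop("no data rows in '", path, "'")
  toks <- strsplit(trimws(data_lines), "[,[:space:]]+")
  ncol <- length(toks[[1]])
  widths <- lengths(toks)
  if (any(widths != ncol))
    stop(sprintf("ragged rows in '%s': line %d has %d fields, expected %d",
                 path, data_nums[which(widths != ncol)[1]],
                 widths[widths != ncol][1], ncol))
  vals <- suppressWarnings(as.numeric(unlist(toks, use.names = FALSE)))
  if (anyNA(vals)) {
    bad_row <- ceiling(which(is.na(vals))[1] / ncol)
    stop(sprintf("non-numeric value in '%s' at line %d", path,
                 data_nums[bad_row]))
  }
  m <- matrix(vals, ncol = ncol, byrow = TRUE)
  eeg_epoch(m, sampling_rate, source_id = basename(path))
}

#' Write an epoch as delimited ASCII text
#'
#' Writes one row per sample, channels as space-separated columns, with 15
#' significant digits so that a read/write round trip preserves the signal
#' to well below any physically meaningful precision.
#'
#' @param epoch An [eeg_epoch()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_epoch_text <- function(epoch, path) {
  stopifnot(inherits(epoch, "eeg_epoch"))
  m <- epoch$samples
  rows <- do.call(paste, c(lapply(seq_len(ncol(m)), function(j)
    sprintf("%.15g", m[, j])), list(sep = " ")))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(rows, con)
  invisible(path)
}

#' Preprocessing configuration
#'
#' Bundles the band-pass limits, epoch duration and filter order used for
#' preprocessing and segmentation. Defaults follow routine clinical EEG
#' practice for this analysis: a 0.5-60 Hz pass band and 12-second epochs.
#'
#' @param band_low_hz Lower pass-band edge in Hz.
#' @param band_high_hz Upper pass-band edge in Hz.
#' @param epoch_seconds Epoch duration in seconds.
#' @param filter_order Order of each Butterworth section.
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(band_low_hz = 0.5, band_high_hz = 60,
                              epoch_seconds = 12, filter_order = 6) {
  if (band_low_hz <= 0 || band_high_hz <= band_low_hz)
    stop("need 0 < band_low_hz < band_high_hz")
  if (epoch_seconds <= 0) stop("epoch_seconds must be positive")
  if (filter_order < 1) stop("filter_order must be >= 1")
  structure(list(band_low_hz = band_low_hz, band_high_hz = band_high_hz,
                 epoch_seconds = epoch_seconds,
                 filter_order = as.integer(filter_order)),
            class = "preprocess_config")
}

#' Zero-phase band-pass filter an epoch
#'
#' Applies a forward-backward (zero-phase) Butterworth band pass, realised
#' as a high-pass/low-pass cascade for numerical stability at low relative
#' cut-offs. Each channel is demeaned first so the high-pass sees no DC
#' step at the epoch edges. Phase distortion would warp the reconstructed
#' state-space geometry, hence the zero-phase design.
#'
#' @param epoch An [eeg_epoch()].
#' @param config A [preprocess_config()].
#' @return A filtered `eeg_epoch` of the same length.
#' @export
bandpass <- function(epoch, config = preprocess_config()) {
  stopifnot(inherits(epoch, "eeg_epoch"))
  fs <- epoch$sampling_rate
  if (config$band_high_hz >= fs / 2)
    stop("band_high_hz must be below the Nyquist frequency ", fs / 2, " Hz")
  hp <- signal::butter(max(2L, config$filter_order %/% 2L),
                       config$band_low_hz / (fs / 2), type = "high")
  lp <- signal::butter(config$filter_order,
                       config$band_high_hz / (fs / 2), type = "low")
  out <- apply(epoch$samples, 2, function(ch)
    signal::filtfilt(lp, signal::filtfilt(hp, ch - mean(ch))))
  eeg_epoch(out, fs, channel_names = epoch$channel_names,
            source_id = epoch$source_id)
}

#' Segment a continuous recording into fixed-length epochs
#'
#' Cuts non-overlapping consecutive epochs of
#' `round(epoch_seconds * sampling_rate)` samples; any trailing remainder is
#' discarded.
#'
#' @param recording An [eeg_epoch()] holding the continuous recording.
#' @param config A [preprocess_config()]; only `epoch_seconds` is used.
#' @return A list of `eeg_epoch` objects (empty, with a warning, if the
#'   recording is shorter than one epoch).
#' @export
segment_epochs <- function(recording, config = preprocess_config()) {
  stopifnot(inherits(recording, "eeg_epoch"))
  len <- round(config$epoch_seconds * recording$sampling_rate)
  n <- n_samples(recording)
  k <- n %/% len
  if (k == 0) {
    warning("recording shorter than one epoch; returning empty list")
    return(list())
  }
  lapply(seq_len(k), function(i) {
    rows <- ((i - 1) * len + 1):(i * len)
    eeg_epoch(recording$samples[rows, , drop = FALSE],
              recording$sampling_rate,
              channel_names = recording$channel_names,
              source_id = sprintf("%s#%d", recording$source_id, i))
  })
}
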