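# Multichannel recording container, CSV/EDF round-trip, and epoching.

#' Construct a multichannel EEG recording
#'
#' @param data Named list of equal-length numeric channel vectors, or a
#'   numeric matrix/data.frame with one column per channel.
#' @param sampling_rate Sampling rate in Hz (> 0).
#' @param subject_id Subject identifier string.
#' @return An `eeg_recording`: list with `channels` (labels), `data` (named
#'   list of numeric vectors), `sampling_rate`, `subject_id`.
#' @export
eeg_recording <- function(data, sampling_rate, subject_id = "subject") {
  sampling_rate <- check_scalar(sampling_rate, "sampling_rate", lower = 1e-9)
  if (is.matrix(data) || is.data.frame(data)) {
    data <- as.data.frame(data)
    data <- stats::setNames(as.list(data), colnames(data))
  }
  stopifnot(is.list(data), length(data) >= 1L)
  if (is.null(names(data)) || any(names(data) == "")) {
    names(data) <- sprintf("ch%02d", seq_along(data))
  }
  lens <- lengths(data)
  if (length(unique(lens)) != 1L) {
    stop("all channels must have the same length", call. = FALSE)
  }
  bad <- names(data)[vapply(data, function(v) anyNA(v) || !all(is.finite(v)), logical(1))]
  if (length(bad) > 0L) {
    stop(sprintf("non-finite samples in channel(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  structure(list(channels = names(data),
                 data = lapply(data, as.numeric),
                 sampling_rate = sampling_rate,
                 subject_id = as.character(subject_id)),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  n <- length(x$data[[1L]])
  cat(sprintf("EEG recording '%s': %d channels x %d samples (%.1f s at %g Hz)\n",
              x$subject_id, length(x$channels), n, n / x$sampling_rate,
              x$sampling_rate))
  invisible(x)
}

#' Write a recording to disk
#'
#' CSV is wide: first column `time` in seconds, then one column per channel
#' with the header row carrying channel labels. EDF is the standard European
#' Data Format (16-bit samples; the physical range is set symmetrically from
#' each channel's max absolute value, so round-trip error is bounded by the
#' 16-bit quantization step).
#'
#' @param rec An `eeg_recording`.
#' @param path Output file path.
#' @param format "csv" or "edf" (default: inferred from the file extension).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = c("auto", "csv", "edf")) {
  stopifnot(inherits(rec, "eeg_recording"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  }
  if (format == "csv") {
    n <- length(rec$data[[1L]])
    df <- data.frame(time = (seq_len(n) - 1L) / rec$sampling_rate)
    for (ch in rec$channels) df[[ch]] <- rec$data[[ch]]
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    write_edf(rec, path)
  }
  invisible(path)
}

#' Read a recording from disk
#'
#' @param path File path.
#' @param format "csv" or "edf" (default: inferred from extension).
#' @param subject_id Optional subject id override (EDF carries its own).
#' @return An `eeg_recording` with validated invariants; channel order is
#'   preserved from the file.
#' @export
read_recording <- function(path, format = c("auto", "csv", "edf"),
                           subject_id = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  }
  if (format == "csv") {
    df <- utils::read.csv(path, check.names = FALSE)
    if (ncol(df) < 2L || names(df)[1L] != "time") {
      stop("wide CSV must have a leading 'time' column plus channel columns",
           call. = FALSE)
    }
    dt <- diff(df$time)
    if (length(dt) < 1L || any(dt <= 0)) stop("non-increasing time column", call. = FALSE)
    fs <- 1 / stats::median(dt)
    eeg_recording(df[-1L], sampling_rate = fs,
                  subject_id = if (is.null(subject_id))
                    sub("\\.[^.]+$", "", basename(path)) else subject_id)
  } else {
    rec <- read_edf(path)
    if (!is.null(subject_id)) rec$subject_id <- as.character(subject_id)
    rec
  }
}

#' Cut a recording into fixed-length epochs
#'
#' Epochs tile each channel with stride `window * (1 - overlap)` samples;
#' trailing partial windows are discarded, giving
#' `floor((N - L) / stride) + 1` epochs per channel. Sample indices are
#' 0-based with half-open windows `[start, start + L)`.
#'
#' @param rec An `eeg_recording`.
#' @param window_seconds Epoch length in seconds (default 4).
#' @param overlap_fraction Fractional overlap in `[0, 1)` (default 0).
#' @param channels Optional subset of channel labels.
#' @return List of `eeg_epoch` objects (fields: samples, sampling_rate,
#'   channel, subject_id, index, start_sample), with a `manifest` attribute
#'   (data.frame: subject, channel, index, start_sample).
#' @export
epoch_signal <- function(rec, window_seconds = 4, overlap_fraction = 0,
                         channels = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  window_seconds <- check_scalar(window_seconds, "window_seconds", lower = 1e-9)
  if (!is.numeric(overlap_fraction) || length(overlap_fraction) != 1L ||
      overlap_fraction < 0 || overlap_fraction >= 1) {
    stop("overlap_fraction must be in [0, 1)", call. = FALSE)
  }
  L <- as.integer(round(window_seconds * rec$sampling_rate))
  if (L < 64L) stop("epoch length must be at least 64 samples", call. = FALSE)
  n <- length(rec$data[[1L]])
  if (L > n) stop("window longer than recording: no epochs can be cut", call. = FALSE)
  stride <- max(1L, as.integer(round(L * (1 - overlap_fraction))))
  starts <- seq.int(0L, n - L, by = stride)  # 0-based
  use_ch <- if (is.null(channels)) rec$channels else {
    missing_ch <- setdiff(channels, rec$channels)
    if (length(missing_ch) > 0L) {
      stop(sprintf("unknown channel(s): %s", paste(missing_ch, collapse = ", ")),
           call. = FALSE)
    }
    channels
  }
  epochs <- list()
  manifest <- list()
  for (ch in use_ch) {
    for (i in seq_along(starts)) {
      s <- starts[i]
      ep <- structure(list(samples = rec$data[[ch]][(s + 1L):(s + L)],
                           sampling_rate = rec$sampling_rate,
                           channel = ch,
                           subject_id = rec$subject_id,
                           index = i,
                           start_sample = s),
                      class = "eeg_epoch")
      epochs[[length(epochs) + 1L]] <- ep
      manifest[[length(manifest) + 1L]] <-
        data.frame(subject = rec$subject_id, channel = ch, index = i,
                   start_sample = s, stringsAsFactors = FALSE)
    }
  }
  attr(epochs, "manifest") <- do.call(rbind, manifest)
  epochs
}

#' @export
print.eeg_epoch <- function(x, ...) {
  cat(sprintf("Epoch %d of '%s' channel %s: %d samples at %g Hz\n",
              x$index, x$subject_id, x$channel, length(x$samples),
              x$sampling_rate))
  invisible(x)
}
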