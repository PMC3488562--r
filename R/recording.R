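#' Multichannel EEG recording
#'
#' `new_recording()` constructs the container used throughout the package for
#' continuous multichannel data: a channels-by-samples numeric matrix in
#' microvolts together with its sampling rate, channel labels, optional 2-D
#' scalp positions, and free-form provenance metadata (filter band, reference
#' state, ...).
#'
#' @param data Numeric matrix, channels x samples, in microvolts.
#' @param fs Sampling rate in Hz (positive scalar).
#' @param labels Character vector of unique channel labels; defaults to
#'   `"ch001"`, `"ch002"`, ...
#' @param positions Optional numeric matrix (channels x 2) of scalp coordinates
#'   on the unit disc.
#' @param meta Named list of provenance notes.
#' @return An object of class `eeg_recording`.
#' @examples
#' rec <- new_recording(matrix(rnorm(4 * 256), 4), fs = 256)
#' rec
#' @export
new_recording <- function(data, fs, labels = NULL, positions = NULL,
                          meta = list()) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (nrow(data) < 2L) stop_domain("a recording needs at least 2 channels")
  if (ncol(data) < 1L) stop_domain("a recording needs at least 1 sample")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop_domain("fs must be a positive scalar, got ", format(fs))
  if (is.null(labels)) labels <- sprintf("ch%03d", seq_len(nrow(data)))
  labels <- as.character(labels)
  if (length(labels) != nrow(data))
    stop_domain("labels length (", length(labels), ") != channel count (",
                nrow(data), ")")
  if (anyDuplicated(labels)) stop_domain("channel labels must be unique")
  if (!is.null(positions)) {
    positions <- as.matrix(positions)
    if (nrow(positions) != nrow(data) || ncol(positions) != 2L)
      stop_domain("positions must be a channels x 2 matrix")
  }
  structure(list(data = data, fs = as.numeric(fs), labels = labels,
                 positions = positions, meta = meta),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), vapply(x$meta, function(m)
      paste(format(unlist(m)), collapse = ","), ""), sep = "=",
      collapse = "; "), "\n")
  invisible(x)
}

#' @export
dim.eeg_recording <- function(x) dim(x$data)

#' Tidy a recording into long format
#'
#' @param x An `eeg_recording`.
#' @param ... Unused.
#' @return A tibble with columns `time` (s), `channel`, `value` (microvolts).
#' @export
tidy.eeg_recording <- function(x, ...) {
  tibble::tibble(
    time = rep((seq_len(ncol(x$data)) - 1) / x$fs, each = nrow(x$data)),
    channel = rep(x$labels, ncol(x$data)),
    value = as.numeric(x$data)
  )
}

#' Event table for a recording
#'
#' Builds the ordered table of event onsets used for epoching. Onsets are
#' 0-based sample indices (the convention used by all window arithmetic in
#' the package) expressed at sampling rate `fs`; codes come from a fixed
#' vocabulary covering oddball stimuli, button presses, and heel-strikes.
#'
#' @param onset_sample Integer vector of 0-based onsets, strictly increasing.
#' @param code Character vector of event codes, one of
#'   `r paste0('\x60', event_codes(), '\x60', collapse = ", ")`.
#' @param fs Sampling rate (Hz) the onsets are expressed in.
#' @return A tibble of class `event_table` with columns `onset_sample`,
#'   `code` and attribute `fs`.
#' @examples
#' event_table(c(40, 100), c("standard", "target"), fs = 512)
#' @export
event_table <- function(onset_sample, code, fs) {
  onset_sample <- as.integer(onset_sample)
  code <- as.character(code)
  if (length(onset_sample) != length(code))
    stop_format("onset_sample and code must have equal length")
  if (any(onset_sample < 0L)) stop_format("onsets must be >= 0")
  if (is.unsorted(onset_sample, strictly = TRUE))
    stop_format("event onsets must be strictly increasing")
  bad <- setdiff(unique(code), event_codes())
  if (length(bad))
    stop_format("unknown event code(s): ", paste(bad, collapse = ", "))
  if (!is.numeric(fs) || fs <= 0) stop_domain("fs must be positive")
  out <- tibble::tibble(onset_sample = onset_sample, code = code)
  attr(out, "fs") <- as.numeric(fs)
  class(out) <- c("event_table", class(out))
  out
}

#' Recognised event codes
#' @return Character vector of the event vocabulary.
#' @export
event_codes <- function() {
  c("standard", "target", "button", "heelstrike_L", "heelstrike_R")
}
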