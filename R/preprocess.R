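# Filtering, decimation, noisy-channel detection, and average re-referencing.
# The canonical order for the comparative pipeline is:
# highpass -> detect_bad_channels -> (removal) -> rereference_average ->
# bandpass -> decimate_by_int.

#' Band-pass filter specification
#'
#' @param center Centre frequency, Hz.
#' @param half_width Half-bandwidth, Hz; the passband is
#'   `center +/- half_width` and must lie strictly above 0 Hz.
#' @param order Butterworth order (default 2, applied per pass direction).
#' @return A list of class `band_spec`.
#' @examples
#' band_spec(4, 2)   # the 4 +/- 2 Hz theta band
#' @export
band_spec <- function(center, half_width, order = 2L) {
  if (center - half_width <= 0)
    stop_domain("band must lie strictly above 0 Hz")
  if (order < 1L) stop_domain("filter order must be >= 1")
  structure(list(center = center, half_width = half_width,
                 order = as.integer(order)), class = "band_spec")
}

apply_filter <- function(data, b, a, zero_phase) {
  flt <- signal::Arma(b = b, a = a)
  t(apply(data, 1L, function(x) {
    if (zero_phase) signal::filtfilt(flt, x) else signal::filter(flt, x)
  }))
}

#' Butterworth band-pass filter
#'
#' Applies a Butterworth band-pass of the stated order per channel. By default
#' the filter runs forward and backward (zero phase distortion, order
#' effectively doubled) because all downstream analysis lives in phase space;
#' `zero_phase = FALSE` gives the causal variant used by the streaming path.
#'
#' @param rec An `eeg_recording`.
#' @param band A [band_spec()]; the band must lie below the Nyquist rate.
#' @param zero_phase Forward-backward filtering (default `TRUE`).
#' @return The filtered recording, with the band recorded in `meta`.
#' @export
bandpass <- function(rec, band = band_spec(4, 2), zero_phase = TRUE) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(band, "band_spec"))
  nyq <- rec$fs / 2
  lo <- band$center - band$half_width
  hi <- band$center + band$half_width
  if (hi >= nyq)
    stop_domain("band edge ", hi, " Hz >= Nyquist (", nyq, " Hz)")
  bt <- signal::butter(band$order, c(lo, hi) / nyq, type = "pass")
  out <- rec
  out$data <- apply_filter(rec$data, bt$b, bt$a, zero_phase)
  out$meta$band <- c(center = band$center, half_width = band$half_width)
  out$meta$zero_phase <- zero_phase
  out
}

#' Butterworth high-pass filter
#'
#' Removes drift and DC offset per channel; zero-phase by default.
#'
#' @param rec An `eeg_recording`.
#' @param cutoff Cutoff frequency in Hz, `0 < cutoff < fs/2`.
#' @param order Butterworth order (default 2).
#' @param zero_phase Forward-backward filtering (default `TRUE`).
#' @return The filtered recording.
#' @export
highpass <- function(rec, cutoff = 1, order = 2L, zero_phase = TRUE) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (cutoff <= 0 || cutoff >= rec$fs / 2)
    stop_domain("cutoff must lie in (0, fs/2)")
  bt <- signal::butter(order, cutoff / (rec$fs / 2), type = "high")
  out <- rec
  out$data <- apply_filter(rec$data, bt$b, bt$a, zero_phase)
  out$meta$highpass <- cutoff
  out
}

#' Integer decimation without interpolation
#'
#' Keeps every `factor`-th sample starting at sample 0 and divides the
#' sampling rate accordingly. No anti-alias filtering or interpolation is
#' applied — the caller must already have band-limited the data below the new
#' Nyquist rate (a warning is issued when the metadata carries no band).
#'
#' @param rec An `eeg_recording`.
#' @param factor Positive integer decimation factor.
#' @return The decimated recording (`fs` divided by `factor`,
#'   `T' = ceiling(T / factor)` samples).
#' @export
decimate_by_int <- function(rec, factor = 10L) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (length(factor) != 1L || is.na(factor) || factor < 1 ||
      factor != round(factor))
    stop_domain("decimation factor must be a positive integer")
  factor <- as.integer(factor)
  if (factor == 1L) return(rec)
  if (is.null(rec$meta$band))
    warning("decimating a recording with no recorded band-pass; ensure the ",
            "signal is band-limited below ", rec$fs / factor / 2, " Hz")
  out <- rec
  out$data <- rec$data[, seq(1L, ncol(rec$data), by = factor), drop = FALSE]
  out$fs <- rec$fs / factor
  out$meta$decimated_by <- factor
  out
}

#' Detect grossly noisy channels
#'
#' Flags channels by three rules, following the standard amplitude/kurtosis/
#' correlation screen for high-density EEG:
#' \enumerate{
#'   \item standard deviation above `std_max` microvolts;
#'   \item excess kurtosis more than `kurt_z` standard deviations from the
#'     across-channel mean kurtosis;
#'   \item Pearson correlation with the mean of its neighbours (channels
#'     within `neighbor_radius` on the scalp layout) below `r_thresh` in more
#'     than `frac_max` of non-overlapping `corr_win`-second windows.
#' }
#'
#' @param rec A high-passed `eeg_recording`; `positions` must be present for
#'   rule 3.
#' @param std_max Rule-1 threshold, microvolts (default 1000).
#' @param kurt_z Rule-2 threshold in across-channel SDs (default 5).
#' @param r_thresh Rule-3 correlation threshold (default 0.4).
#' @param frac_max Rule-3 maximum low-correlation window fraction
#'   (default 0.01).
#' @param corr_win Rule-3 window length, seconds (default 1).
#' @param neighbor_radius Neighbourhood radius in layout units (default 0.25
#'   on the unit disc).
#' @param rules Which rules to run (default all three).
#' @return A tibble of class `channel_qc_report`: one row per channel with
#'   `channel`, `label`, `sd`, `kurtosis`, `kurtosis_z`, `low_corr_frac`,
#'   logical `rule_sd`/`rule_kurtosis`/`rule_corr`, and `rejected`.
#' @export
detect_bad_channels <- function(rec, std_max = 1000, kurt_z = 5,
                                r_thresh = 0.4, frac_max = 0.01,
                                corr_win = 1, neighbor_radius = 0.25,
                                rules = c("sd", "kurtosis", "corr")) {
  stopifnot(inherits(rec, "eeg_recording"))
  rules <- match.arg(rules, several.ok = TRUE)
  N <- nrow(rec$data)
  sds <- apply(rec$data, 1L, stats::sd)
  kur <- apply(rec$data, 1L, excess_kurtosis)
  kz <- if (stats::sd(kur) > 0) (kur - mean(kur)) / stats::sd(kur)
        else rep(0, N)
  r1 <- if ("sd" %in% rules) sds > std_max else rep(FALSE, N)
  r2 <- if ("kurtosis" %in% rules) abs(kz) > kurt_z else rep(FALSE, N)
  frac <- rep(NA_real_, N)
  r3 <- rep(FALSE, N)
  if ("corr" %in% rules) {
    if (is.null(rec$positions))
      stop("neighbour-correlation rule requested but the recording has no ",
           "channel positions")
    wlen <- max(2L, round(corr_win * rec$fs))
    nwin <- floor(ncol(rec$data) / wlen)
    if (nwin < 1L) stop_domain("recording shorter than one correlation window")
    dmat <- as.matrix(stats::dist(rec$positions))
    # channels already flagged by the amplitude/kurtosis rules are excluded
    # from neighbour references, so one gross channel cannot poison the
    # correlation screen of its neighbours
    ok_ref <- !(r1 | r2)
    for (n in seq_len(N)) {
      nb <- which(dmat[n, ] <= neighbor_radius & seq_len(N) != n & ok_ref)
      if (!length(nb)) { frac[n] <- NA_real_; next }
      ref <- if (length(nb) == 1L) rec$data[nb, ]
             else colMeans(rec$data[nb, , drop = FALSE])
      low <- 0L
      for (w in seq_len(nwin)) {
        idx <- ((w - 1L) * wlen + 1L):(w * wlen)
        r <- suppressWarnings(stats::cor(rec$data[n, idx], ref[idx]))
        if (is.na(r) || r < r_thresh) low <- low + 1L
      }
      frac[n] <- low / nwin
    }
    r3 <- !is.na(frac) & frac > frac_max
  }
  out <- tibble::tibble(channel = seq_len(N) - 1L, label = rec$labels,
                        sd = sds, kurtosis = kur, kurtosis_z = kz,
                        low_corr_frac = frac,
                        rule_sd = r1, rule_kurtosis = r2, rule_corr = r3,
                        rejected = r1 | r2 | r3)
  class(out) <- c("channel_qc_report", class(out))
  out
}

#' Average re-reference
#'
#' Subtracts, at every sample, the mean of the retained channels from each
#' retained channel; excluded (rejected) channels are dropped from the output.
#' After this the across-channel mean is zero at every sample.
#'
#' @param rec An `eeg_recording`.
#' @param exclude 0-based indices of channels to exclude and drop.
#' @return The re-referenced recording.
#' @export
rereference_average <- function(rec, exclude = integer(0)) {
  stopifnot(inherits(rec, "eeg_recording"))
  keep <- setdiff(seq_len(nrow(rec$data)) - 1L, as.integer(exclude))
  if (length(keep) < 2L)
    stop_domain("average re-reference needs at least 2 retained channels")
  data <- rec$data[keep + 1L, , drop = FALSE]
  data <- sweep(data, 2L, colMeans(data))
  out <- rec
  out$data <- data
  out$labels <- rec$labels[keep + 1L]
  if (!is.null(rec$positions))
    out$positions <- rec$positions[keep + 1L, , drop = FALSE]
  out$meta$reference <- "average"
  out$meta$n_excluded <- length(exclude)
  out
}
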