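# Instantaneous phase extraction and sliding-window weighted phase lag index
# (WPLI) over all channel pairs.
#
# WPLI quantifies how consistently one channel's phase lags another's,
# weighting phase differences by their sine so that +/-90 degree lags count
# maximally and zero-lag (volume-conducted or common-artifact) coupling is
# ignored: WPLI = |<sin dPhi>| / <|sin dPhi|> over a window.

#' Sliding-window geometry
#'
#' @param window_len Samples per window (default 25, ~488 ms at 51.2 Hz).
#' @param hop Samples between window starts (default 12, ~234 ms; roughly
#'   half-window overlap).
#' @return A list of class `window_spec`.
#' @export
window_spec <- function(window_len = 25L, hop = 12L) {
  window_len <- as.integer(window_len); hop <- as.integer(hop)
  if (hop < 1L || hop > window_len)
    stop_domain("hop must satisfy 1 <= hop <= window_len")
  structure(list(window_len = window_len, hop = hop), class = "window_spec")
}

#' Instantaneous phase via the analytic signal
#'
#' Computes, per channel, the instantaneous phase
#' `phi_t = atan2(H(x)_t, x_t)` where `H` is the Hilbert transform (the
#' imaginary part of the analytic signal). The input should be narrowband —
#' a warning is issued when the recording metadata carries no band. The
#' default method builds the analytic signal in the frequency domain; the
#' `"fir"` method uses a causal FIR Hilbert transformer with group-delay
#' compensation and is the one used by the streaming pipeline.
#'
#' @param rec A band-limited `eeg_recording`.
#' @param method `"fft"` (exact, offline) or `"fir"` (causal approximation).
#' @param fir_length Odd tap count of the FIR transformer (default 101).
#' @return A list of class `phase_set` with elements `phases` (channels x
#'   samples, radians in `(-pi, pi]`), `fs`, and `source_meta`. Channels that
#'   are identically zero get `NaN` phases with a warning.
#' @export
analytic_phase <- function(rec, method = c("fft", "fir"), fir_length = 101L) {
  stopifnot(inherits(rec, "eeg_recording"))
  method <- match.arg(method)
  if (is.null(rec$meta$band))
    warning("computing instantaneous phase of a recording with no recorded ",
            "band-pass; phase is only meaningful for narrowband signals")
  ph <- matrix(NA_real_, nrow(rec$data), ncol(rec$data))
  zero_ch <- logical(nrow(rec$data))
  for (n in seq_len(nrow(rec$data))) {
    x <- rec$data[n, ]
    if (all(x == 0)) { zero_ch[n] <- TRUE; ph[n, ] <- NaN; next }
    h <- switch(method,
                fft = hilbert_fft(x),
                fir = hilbert_fir(x, fir_length))
    ph[n, ] <- atan2(h, x)
  }
  if (any(zero_ch))
    warning("phase undefined for all-zero channel(s): ",
            paste(which(zero_ch) - 1L, collapse = ", "))
  structure(list(phases = ph, fs = rec$fs,
                 source_meta = rec$meta[c("band", "decimated_by")]),
            class = "phase_set")
}

# Imaginary part of the analytic signal, frequency-domain construction:
# double positive frequencies, zero negative ones.
hilbert_fft <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Im(stats::fft(X * h, inverse = TRUE) / n)
}

# Causal FIR Hilbert transform with group-delay compensation: the output at
# sample t uses inputs up to t, delayed by (L-1)/2 samples; we shift back so
# it aligns with x, leaving (L-1)/2 invalid samples at the end (padded by
# zero-order hold). Used by the streaming path, where the shift is handled
# explicitly.
hilbert_fir <- function(x, fir_length = 101L) {
  h <- fir_hilbert_taps(fir_length)
  d <- (fir_length - 1L) / 2L
  y <- fir_filter_state(h, c(x, numeric(d)))$y
  y[(d + 1L):(d + length(x))]
}

#' @export
print.phase_set <- function(x, ...) {
  cat(sprintf("<phase_set> %d channels x %d samples @ %g Hz\n",
              nrow(x$phases), ncol(x$phases), x$fs))
  invisible(x)
}

#' Pairwise phase differences
#'
#' For every pair `(i, j)` and sample `t`, computes
#' `dPhi = wrap(phi_i - phi_j)` into `(-pi, pi]`.
#'
#' @param ph A [analytic_phase()] result.
#' @param pairs A [make_pair_index()] for the same channel count.
#' @return Numeric matrix, pairs x samples, of wrapped phase differences.
#' @export
phase_differences <- function(ph, pairs) {
  stopifnot(inherits(ph, "phase_set"))
  N <- nrow(ph$phases)
  if (max(pairs$j) >= N) stop_domain("pair index exceeds channel count")
  wrap_phase(ph$phases[pairs$i + 1L, , drop = FALSE] -
             ph$phases[pairs$j + 1L, , drop = FALSE])
}

#' WPLI of a single window of phase differences
#'
#' `|sum(sin dPhi)| / sum(|sin dPhi|)`, in `[0, 1]`. When the denominator is
#' zero (every difference a multiple of pi — no lagged-coupling evidence at
#' all) the value is 0 by convention.
#'
#' @param dphi Numeric vector of phase differences (radians) over one window.
#' @return Scalar in `[0, 1]`.
#' @examples
#' wpli_window(c(pi / 2, pi / 2, -pi / 2))  # 1/3
#' @export
wpli_window <- function(dphi) {
  if (!length(dphi)) stop_domain("empty window")
  s <- sin(dphi)
  den <- sum(abs(s))
  if (den <= .Machine$double.eps * length(s)) return(0)
  abs(sum(s)) / den
}

# Number of sliding windows that fit: floor((T - window_len)/hop) + 1.
n_windows <- function(T, win) {
  if (T < win$window_len) stop_domain("series shorter than one window")
  (T - win$window_len) %/% win$hop + 1L
}

#' Sliding-window WPLI over all pairs
#'
#' Applies [wpli_window()] to every pair over windows starting at samples
#' `0, hop, 2 hop, ...` (0-based, half-open `[s, s + window_len)`). Window
#' centres are reported at `(s + (window_len - 1)/2) / fs` seconds.
#'
#' @param ph A [analytic_phase()] result.
#' @param pairs A [make_pair_index()]; defaults to all pairs.
#' @param win A [window_spec()].
#' @return A `pair_series` of kind `"wpli"`.
#' @export
wpli_sliding <- function(ph, pairs = NULL, win = window_spec()) {
  stopifnot(inherits(ph, "phase_set"), inherits(win, "window_spec"))
  if (is.null(pairs)) pairs <- make_pair_index(nrow(ph$phases))
  T <- ncol(ph$phases)
  nw <- n_windows(T, win)
  dphi <- phase_differences(ph, pairs)
  s <- sin(dphi)
  # cumulative sums make each window sum O(1)
  cs <- cbind(0, t(apply(s, 1L, cumsum)))
  ca <- cbind(0, t(apply(abs(s), 1L, cumsum)))
  starts <- (seq_len(nw) - 1L) * win$hop            # 0-based
  num <- abs(cs[, starts + win$window_len + 1L, drop = FALSE] -
               cs[, starts + 1L, drop = FALSE])
  den <- ca[, starts + win$window_len + 1L, drop = FALSE] -
    ca[, starts + 1L, drop = FALSE]
  vals <- ifelse(den <= .Machine$double.eps * win$window_len, 0, num / den)
  vals <- pmin(pmax(vals, 0), 1)
  centers <- (starts + (win$window_len - 1) / 2) / ph$fs
  new_pair_series(vals, centers, win$window_len, win$hop, ph$fs, pairs,
                  kind = "wpli")
}

#' Heel-strike-locked epochs of a pair series
#'
#' Convenience wrapper over [epoch_lock()] that keeps only heel-strike events
#' (either foot) and epochs the series around them — the view used to check
#' that gait-locked artifact does not masquerade as connectivity deflections.
#'
#' @param series A `pair_series`.
#' @param events An [event_table()] containing `heelstrike_L`/`heelstrike_R`
#'   codes.
#' @param pre,post Epoch extent in seconds before/after each strike.
#' @return An `epoch_set` (see [epoch_lock()]).
#' @export
heelstrike_locked <- function(series, events, pre = 0.5, post = 0.5) {
  hs <- events[events$code %in% c("heelstrike_L", "heelstrike_R"), ]
  if (!nrow(hs)) stop_domain("no heel-strike events in the table")
  attr(hs, "fs") <- attr(events, "fs")
  class(hs) <- class(events)
  epoch_lock(series, hs, code = c("heelstrike_L", "heelstrike_R"),
             pre = pre, post = post)
}
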