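#' Enumerate unordered channel pairs
#'
#' Because the phase-lag index is undirected, only the `N(N-1)/2` unordered
#' channel pairs are materialised rather than the full `N^2` matrix. Pairs are
#' listed in lexicographic order `(i, j)` with `i < j`, using 0-based channel
#' indices to match the sample-index convention.
#'
#' @param n_channels Number of channels (>= 2).
#' @return A tibble of class `pair_index` with integer columns `i`, `j`
#'   (0-based, `i < j`) and attribute `n_channels`.
#' @examples
#' make_pair_index(3)
#' nrow(make_pair_index(248))  # 30628
#' @export
make_pair_index <- function(n_channels) {
  n_channels <- as.integer(n_channels)
  if (length(n_channels) != 1L || is.na(n_channels) || n_channels < 2L)
    stop_domain("n_channels must be an integer >= 2")
  idx <- utils::combn(n_channels, 2L) - 1L
  out <- tibble::tibble(i = idx[1L, ], j = idx[2L, ])
  attr(out, "n_channels") <- n_channels
  class(out) <- c("pair_index", class(out))
  out
}

#' Mirror a pair-indexed vector into a square matrix
#'
#' @param values Numeric vector, one value per pair of `pairs`.
#' @param pairs A `pair_index`.
#' @param diag Value to place on the diagonal (default `NA`).
#' @return A symmetric `n_channels x n_channels` matrix.
#' @export
pairs_to_square <- function(values, pairs, diag = NA_real_) {
  n <- attr(pairs, "n_channels")
  if (length(values) != nrow(pairs))
    stop_domain("values length != pair count")
  m <- matrix(diag, n, n)
  ii <- pairs$i + 1L; jj <- pairs$j + 1L
  m[cbind(ii, jj)] <- values
  m[cbind(jj, ii)] <- values
  m
}

#' Sliding-window and pair-series container
#'
#' Holds a pairs-by-windows matrix of WPLI or WPLI-stability values together
#' with its window geometry: `window_len` samples per window, `hop` samples
#' between window starts (both at the rate `fs` of the phase series), and the
#' time of each window centre in seconds.
#'
#' @param values Numeric matrix, pairs x windows.
#' @param window_centers Window-centre times in seconds, strictly increasing.
#' @param window_len,hop Window geometry in samples.
#' @param fs Sampling rate (Hz) of the underlying series.
#' @param pair_index A [make_pair_index()] object with matching pair count.
#' @param kind `"wpli"` (values in `[0, 1]`) or `"wplis"` (values `>= 0`).
#' @return An object of class `pair_series`.
#' @export
new_pair_series <- function(values, window_centers, window_len, hop, fs,
                            pair_index, kind = c("wpli", "wplis")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (nrow(values) != nrow(pair_index))
    stop_domain("row count (", nrow(values), ") != pair count (",
                nrow(pair_index), ")")
  if (length(window_centers) != ncol(values))
    stop_domain("window_centers length != window count")
  if (is.unsorted(window_centers, strictly = TRUE))
    stop_domain("window_centers must be strictly increasing")
  fin <- values[is.finite(values)]
  if (kind == "wpli" && length(fin) &&
      (min(fin) < -1e-12 || max(fin) > 1 + 1e-12))
    stop_domain("wpli values must lie in [0, 1]")
  if (kind == "wplis" && length(fin) && min(fin) < -1e-12)
    stop_domain("wplis values must be >= 0")
  structure(list(values = values, window_centers = as.numeric(window_centers),
                 window_len = as.integer(window_len), hop = as.integer(hop),
                 fs = as.numeric(fs), pair_index = pair_index, kind = kind),
            class = "pair_series")
}

#' @export
print.pair_series <- function(x, ...) {
  cat(sprintf("<pair_series:%s> %d pairs x %d windows (win %d, hop %d @ %g Hz)\n",
              x$kind, nrow(x$values), ncol(x$values), x$window_len, x$hop, x$fs))
  invisible(x)
}

#' Tidy a pair series into long format
#'
#' @param x A `pair_series`.
#' @param ... Unused.
#' @return Tibble with columns `i`, `j` (0-based channel indices), `time`
#'   (window centre, s), `value`.
#' @export
tidy.pair_series <- function(x, ...) {
  np <- nrow(x$values); nw <- ncol(x$values)
  tibble::tibble(
    i = rep(x$pair_index$i, nw),
    j = rep(x$pair_index$j, nw),
    time = rep(x$window_centers, each = np),
    value = as.numeric(x$values)
  )
}
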