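# Internal numerical helpers shared across modules.

#' Wrap angles into (-pi, pi]
#'
#' Maps arbitrary angles in radians onto the principal interval `(-pi, pi]`.
#' All phase arithmetic in the package goes through this function (or through
#' `atan2()`, which lands in the same interval) so that phase differences are
#' never formed by naive subtraction.
#'
#' @param x Numeric vector or matrix of angles in radians.
#' @return Object of the same shape with values in `(-pi, pi]`.
#' @examples
#' wrap_phase(c(0, pi, -pi, 3.0 - (-3.0)))
#' @export
wrap_phase <- function(x) {
  # pi - ((pi - x) mod 2pi) maps onto (-pi, pi]; both boundaries go to +pi
  out <- pi - ((pi - x) %% (2 * pi))
  attributes(out) <- attributes(x)
  out
}

# Direct-form II transposed IIR filter with explicit carried state, so the
# causal path gives bit-identical results whether the signal arrives in one
# chunk or many. state has length max(length(a), length(b)) - 1.
iir_filter_state <- function(b, a, x, state = NULL) {
  b <- as.numeric(b); a <- as.numeric(a)
  if (a[1] != 1) { b <- b / a[1]; a <- a / a[1] }
  n <- max(length(a), length(b))
  b <- c(b, rep(0, n - length(b)))
  a <- c(a, rep(0, n - length(a)))
  if (is.null(state)) state <- rep(0, n - 1)
  stopifnot(length(state) == n - 1)
  y <- numeric(length(x))
  z <- state
  for (t in seq_along(x)) {
    xt <- x[t]
    yt <- b[1] * xt + z[1]
    if (n > 2) {
      for (k in 1:(n - 2)) z[k] <- b[k + 1] * xt + z[k + 1] - a[k + 1] * yt
    }
    z[n - 1] <- b[n] * xt - a[n] * yt
    y[t] <- yt
  }
  list(y = y, state = z)
}

# FIR filter with carried state (used by the streaming Hilbert transformer).
fir_filter_state <- function(h, x, state = NULL) {
  L <- length(h)
  if (is.null(state)) state <- rep(0, L - 1)
  xx <- c(state, x)
  y <- as.numeric(stats::filter(xx, h, method = "convolution", sides = 1))
  y <- y[L:length(xx)]
  list(y = y, state = xx[(length(xx) - L + 2):length(xx)])
}

# Type-III FIR Hilbert transformer (antisymmetric, odd length) by the window
# method. Group delay is (L-1)/2 samples; callers compensate by shifting.
fir_hilbert_taps <- function(length_taps = 101L) {
  stopifnot(length_taps %% 2L == 1L, length_taps >= 3L)
  m <- (length_taps - 1L) / 2L
  n <- seq(-m, m)
  h <- ifelse(n %% 2 == 0, 0, 2 / (pi * n))
  w <- 0.54 + 0.46 * cos(pi * n / m)  # Hamming
  h * w
}

stop_domain <- function(...) {
  stop(structure(class = c("phaselagr_domain_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_format <- function(...) {
  stop(structure(class = c("phaselagr_format_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

# Sample excess kurtosis (fourth central moment / variance^2 - 3).
excess_kurtosis <- function(x) {
  x <- x - mean(x)
  m2 <- mean(x^2)
  if (m2 == 0) return(0)
  mean(x^4) / m2^2 - 3
}
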