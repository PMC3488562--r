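# Shared fixture builders and independent oracles. Everything is generated
# in code at test time; no stored binary data.

# sinusoidal recording: one row per frequency (Hz); amplitude in uV
sine_recording <- function(freqs, fs = 512, dur = 4, amp = 10, phase = 0) {
  t <- (seq_len(round(dur * fs)) - 1) / fs
  data <- t(vapply(freqs, function(f) amp * sin(2 * pi * f * t + phase),
                   numeric(length(t))))
  new_recording(data, fs = fs)
}

# independent analytic-signal oracle: explicit one-sided spectrum via the
# sign-function formulation H(x) = Re(ifft(-i * sgn(f) * fft(x)))
oracle_hilbert <- function(x) {
  n <- length(x)
  # positive bins get +1, negative bins -1, DC (and Nyquist for even n) 0
  sgn <- numeric(n)
  if (n %% 2 == 0) {
    sgn[2:(n / 2)] <- 1
    sgn[(n / 2 + 2):n] <- -1
  } else {
    sgn[2:((n + 1) / 2)] <- 1
    sgn[((n + 3) / 2):n] <- -1
  }
  Re(stats::fft(-1i * sgn * stats::fft(x), inverse = TRUE) / n)
}

# brute-force sliding WPLI: explicit loops over pairs and windows
naive_wpli_sliding <- function(phases, fs, window_len, hop) {
  N <- nrow(phases); T <- ncol(phases)
  pairs <- which(upper.tri(matrix(0, N, N)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  starts <- seq(0, T - window_len, by = hop)
  out <- matrix(NA_real_, nrow(pairs), length(starts))
  for (p in seq_len(nrow(pairs))) {
    i <- pairs[p, 1]; j <- pairs[p, 2]
    for (w in seq_along(starts)) {
      idx <- (starts[w] + 1):(starts[w] + window_len)
      d <- phases[i, idx] - phases[j, idx]
      d <- atan2(sin(d), cos(d))
      s <- sin(d)
      den <- sum(abs(s))
      out[p, w] <- if (den < 1e-300) 0 else abs(sum(s)) / den
    }
  }
  out
}

# brute-force trailing coefficient of variation over k values
naive_wplis <- function(values, k) {
  np <- nrow(values); nw <- ncol(values) - k + 1
  out <- matrix(NA_real_, np, nw)
  for (p in seq_len(np)) {
    for (w in seq_len(nw)) {
      x <- values[p, w:(w + k - 1)]
      m <- mean(x)
      out[p, w] <- if (m <= 0) 0 else stats::sd(x) / m
    }
  }
  out
}

# write a minimal single-record-per-second EDF file (16-bit) for reader tests
write_test_edf <- function(path, data, fs, phys_range = c(-500, 500)) {
  ns <- nrow(data)
  n_rec <- ncol(data) / fs
  stopifnot(n_rec == round(n_rec))
  pad <- function(x, w) {
    s <- substr(as.character(x), 1, w)
    paste0(s, strrep(" ", w - nchar(s)))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(pad("0", 8), con, eos = NULL)
  writeChar(pad("test patient", 80), con, eos = NULL)
  writeChar(pad("test recording", 80), con, eos = NULL)
  writeChar(pad("01.01.20", 8), con, eos = NULL)
  writeChar(pad("00.00.00", 8), con, eos = NULL)
  writeChar(pad(256 + ns * 256, 8), con, eos = NULL)
  writeChar(pad("", 44), con, eos = NULL)
  writeChar(pad(n_rec, 8), con, eos = NULL)
  writeChar(pad(1, 8), con, eos = NULL)
  writeChar(pad(ns, 4), con, eos = NULL)
  for (i in seq_len(ns)) writeChar(pad(sprintf("ch%d", i), 16), con, eos = NULL)
  for (i in seq_len(ns)) writeChar(pad("AgAgCl", 80), con, eos = NULL)
  for (i in seq_len(ns)) writeChar(pad("uV", 8), con, eos = NULL)
  for (i in seq_len(ns)) writeChar(pad(phys_range[1], 8), con, eos = NULL)
  for (i in seq_len(ns)) writeChar(pad(phys_range[2], 8), con, eos = NULL)
  for (i in seq_len(ns)) writeChar(pad(-32768, 8), con, eos = NULL)
  for (i in seq_len(ns)) writeChar(pad(32767, 8), con, eos = NULL)
  for (i in seq_len(ns)) writeChar(pad("", 80), con, eos = NULL)
  for (i in seq_len(ns)) writeChar(pad(fs, 8), con, eos = NULL)
  for (i in seq_len(ns)) writeChar(pad("", 32), con, eos = NULL)
  gain <- (phys_range[2] - phys_range[1]) / 65535
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      seg <- data[i, ((r - 1) * fs + 1):(r * fs)]
      dig <- round((seg - phys_range[1]) / gain) - 32768
      writeBin(as.integer(pmin(pmax(dig, -32768), 32767)), con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}

# 32-channel QC fixture: common-source-driven clean channels plus one
# high-variance, one heavy-tailed (Laplacian), one decorrelated channel
qc_fixture <- function(seed = 5) {
  cfg <- sim_config(n_channels = 32, duration = 60, common_source_gain = 2,
                    bad_channels = data.frame(index = 3L, sigma = 2000),
                    seed = seed)
  rec <- generate_recording(cfg, NULL)$recording
  n <- ncol(rec$data)
  withr::with_seed(seed + 1, {
    rec$data[12, ] <- stats::rexp(n, 1 / 30) * sample(c(-1, 1), n, TRUE)
    rec$data[21, ] <- stats::rnorm(n, 0, 25)
  })
  list(rec = rec, bad = c(3L, 11L, 20L))
}
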