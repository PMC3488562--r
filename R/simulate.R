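# Synthetic multichannel EEG with known phase-lag structure, zero-lag common
# sources, gait-locked artifact bursts, grossly noisy channels, and oddball
# event schedules. Every downstream stage of the pipeline can be validated
# against the ground truth this module returns.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# O(T) centred moving average used to give phase jitter a finite correlation
# time; white jitter would be removed entirely by the analysis band-pass.
smooth_ma <- function(x, width) {
  width <- max(1L, as.integer(width))
  cs <- cumsum(c(0, x))
  n <- length(x)
  half <- width %/% 2L
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Simulation configuration
#'
#' Assembles the parameters of the synthetic-EEG generator. The defaults
#' emulate the recording conditions the pipeline targets: 248-channel EEG at
#' 512 Hz, a 4 Hz carrier (the analysis band), 20 uV oscillation amplitude,
#' and an event-locked stabilisation of phase-lagged coupling from 0.3 s to
#' 1.0 s after each target stimulus.
#'
#' @param n_channels Channel count (default 248).
#' @param fs Sampling rate, Hz (default 512).
#' @param duration Recording length, seconds.
#' @param carrier_freq Oscillation frequency, Hz (default 4).
#' @param amplitude Oscillation amplitude, microvolts (default 20).
#' @param coupled_pairs Data frame with columns `i`, `j` (0-based channel
#'   indices), `lag` (radians channel `j` lags channel `i` by) and `kappa`
#'   (phase-jitter concentration; jitter SD is `kappa^-0.5` rad). Default:
#'   none. `kappa = 1.5` is a realistic concentration for scalp EEG in the
#'   theta band (the phase-lag index then occupies the mid-range rather than
#'   saturating at 1).
#' @param common_source_gain Per-channel mixing weight (scalar recycled) for a
#'   single zero-lag common source of amplitude `amplitude`; 0 disables.
#' @param gait_period Heel-strike period in seconds; 0 disables the gait
#'   artifact.
#' @param gait_amplitude Peak amplitude of the heel-strike impact transient,
#'   microvolts (default 1000).
#' @param gait_inband Amplitude of the continuous gait-locked in-band
#'   component (the harmonic of the gait frequency nearest `carrier_freq`),
#'   microvolts (default 60, i.e. 3x the oscillation amplitude). Like the
#'   impact transient it is added identically (zero lag) to all channels.
#' @param bad_channels Data frame with columns `index` (0-based) and `sigma`
#'   (uV): channels overwritten with white noise of that SD.
#' @param event_modulation List with `onset`, `offset` (seconds after each
#'   target stimulus) and `kappa_multiplier` (> 0): within the interval,
#'   every coupled pair's `kappa` is multiplied, increasing (multiplier > 1)
#'   the stability of the designed lag.
#' @param noise_sd Gaussian sensor-noise SD, microvolts (default 5).
#' @param jitter_tau Correlation time of the phase jitter, seconds
#'   (default 0.2).
#' @param drift_sd Per-sample SD of each oscillator's slow random-walk phase
#'   drift, radians (default 0.03): uncoupled channels decohere over seconds.
#' @param erp List with `amplitude` (uV; 0 disables), `window` (seconds after
#'   target onset) and `channels` (0-based; `NULL` = first half): adds a
#'   fixed-latency half-sine voltage deflection so the conventional
#'   voltage-averaging path has something to recover.
#' @param seed Integer seed; the generator is deterministic given the
#'   configuration.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_channels = 248L, fs = 512, duration = 300,
                       carrier_freq = 4, amplitude = 20,
                       coupled_pairs = NULL, common_source_gain = 0,
                       gait_period = 0, gait_amplitude = 1000,
                       gait_inband = 60, bad_channels = NULL,
                       event_modulation = list(onset = 0.3, offset = 1.0,
                                               kappa_multiplier = 4),
                       noise_sd = 5, jitter_tau = 0.2, drift_sd = 0.03,
                       erp = list(amplitude = 0, window = c(0.3, 0.7),
                                  channels = NULL),
                       seed = 1L) {
  if (duration * fs < 50)
    stop_domain("duration * fs must cover at least two analysis windows")
  if (!is.null(coupled_pairs)) {
    coupled_pairs <- tibble::as_tibble(coupled_pairs)
    stopifnot(all(c("i", "j", "lag", "kappa") %in% names(coupled_pairs)))
    if (any(coupled_pairs$kappa <= 0)) stop_domain("kappa must be > 0")
    if (any(coupled_pairs$i >= n_channels | coupled_pairs$j >= n_channels))
      stop_domain("coupled pair index out of range")
  }
  if (event_modulation$kappa_multiplier <= 0)
    stop_domain("kappa_multiplier must be > 0")
  if (gait_amplitude < 0) stop_domain("gait_amplitude must be >= 0")
  if (!is.null(bad_channels)) {
    bad_channels <- tibble::as_tibble(bad_channels)
    stopifnot(all(c("index", "sigma") %in% names(bad_channels)))
  }
  structure(list(n_channels = as.integer(n_channels), fs = fs,
                 duration = duration, carrier_freq = carrier_freq,
                 amplitude = amplitude, coupled_pairs = coupled_pairs,
                 common_source_gain = common_source_gain,
                 gait_period = gait_period, gait_amplitude = gait_amplitude,
                 gait_inband = gait_inband, bad_channels = bad_channels,
                 event_modulation = event_modulation, noise_sd = noise_sd,
                 jitter_tau = jitter_tau, drift_sd = drift_sd, erp = erp,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate an oddball stimulus schedule
#'
#' Stimuli of fixed duration are presented in a stream with inter-stimulus
#' intervals drawn uniformly from `isi_range`; each stimulus is independently
#' flagged as a rare target with probability `p_target`, otherwise as a
#' standard. This is the classic oddball paradigm (frequent standards, rare
#' targets eliciting a P300-like response).
#'
#' @param duration Schedule length, seconds.
#' @param fs Sampling rate (Hz) for expressing onsets as sample indices.
#' @param p_target Probability a stimulus is a target (default 0.2).
#' @param stim_dur Stimulus presentation time, seconds (default 0.5).
#' @param isi_range Length-2 numeric, uniform inter-stimulus interval bounds
#'   in seconds (default `c(0.5, 1.5)`).
#' @param seed Integer seed (the schedule is deterministic given it).
#' @return An [event_table()] of `standard`/`target` onsets.
#' @export
generate_oddball_schedule <- function(duration, fs, p_target = 0.2,
                                      stim_dur = 0.5,
                                      isi_range = c(0.5, 1.5), seed = 1L) {
  if (isi_range[1] > isi_range[2])
    stop_domain("isi_range minimum exceeds maximum")
  if (p_target <= 0 || p_target >= 1)
    stop_domain("p_target must be strictly between 0 and 1")
  if (duration <= stim_dur + isi_range[2])
    stop_domain("duration too short for a single stimulus + ISI")
  with_seed(seed, {
    onsets <- numeric(0)
    t <- stats::runif(1, isi_range[1], isi_range[2])
    while (t + stim_dur <= duration) {
      onsets <- c(onsets, t)
      t <- t + stim_dur + stats::runif(1, isi_range[1], isi_range[2])
    }
    codes <- ifelse(stats::runif(length(onsets)) < p_target,
                    "target", "standard")
    event_table(floor(onsets * fs), codes, fs = fs)
  })
}

# Heel-strike impact transient: a 0.25 s Hann-windowed burst of high
# harmonics of the gait frequency (mechanical impact energy, 14-20 Hz for a
# 1.25 s gait cycle), peak-normalised. Together with the continuous in-band
# pedestal added in generate_recording() this forms the gait-locked artifact:
# the impact carries the near-strike energy, the pedestal the rhythmic
# in-band contamination that a phase-lag metric must reject.
gait_template <- function(fs, gait_period, gait_amplitude, dur = 0.25) {
  L <- round(dur * fs)
  tau <- (seq_len(L) - 1) / fs - dur / 2
  f0 <- 1 / gait_period
  ks <- round(14.4 / f0) + c(0L, 1L, 2L)   # wave packet near 14.4-16 Hz
  g <- rowSums(vapply(ks, function(k) cos(2 * pi * k * f0 * tau),
                      numeric(L)))
  w <- 0.5 * (1 + cos(2 * pi * tau / dur))
  g <- g * w
  g / max(abs(g)) * gait_amplitude
}

#' Generate a synthetic recording with ground truth
#'
#' Builds a channels-by-samples recording from the configuration: each channel
#' is a narrowband oscillator with slow phase drift; for every coupled pair
#' `(i, j, lag, kappa)` channel `j`'s phase equals channel `i`'s phase minus
#' `lag` plus smooth wrapped-Gaussian jitter of SD `kappa^-0.5`; within each
#' target-event modulation interval `kappa` is multiplied by
#' `kappa_multiplier` (a more stable lag, hence a dip in the stability
#' statistic downstream). A single zero-lag common source, a zero-lag
#' gait-locked artifact burst at every heel-strike, overwritten noisy
#' channels, Gaussian sensor noise, and an optional fixed-latency voltage
#' deflection complete the signal model.
#'
#' @param cfg A [sim_config()].
#' @param events An [event_table()] of stimulus onsets (targets drive the
#'   modulation), or `NULL` for none.
#' @return A list with elements `recording` (an `eeg_recording`) and `truth`
#'   (class `sim_ground_truth`: coupled pairs, modulation intervals with
#'   truncation flags, heel-strike onsets and event table, bad channels).
#' @export
generate_recording <- function(cfg, events = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  fs <- cfg$fs
  T <- round(cfg$duration * fs)
  N <- cfg$n_channels
  if (!is.null(events) && nrow(events) &&
      max(events$onset_sample) >= cfg$duration * attr(events, "fs"))
    stop_domain("events extend past the end of the recording")
  with_seed(cfg$seed, {
    tvec <- (seq_len(T) - 1) / fs
    omega <- 2 * pi * cfg$carrier_freq
    # independent base oscillator phase per channel
    phases <- matrix(0, N, T)
    for (n in seq_len(N)) {
      drift <- cumsum(stats::rnorm(T, 0, cfg$drift_sd))
      phases[n, ] <- omega * tvec + stats::runif(1, -pi, pi) + drift
    }
    # target-event modulation intervals (seconds), truncated at the end
    mod <- tibble::tibble(start = numeric(0), end = numeric(0),
                          truncated = logical(0))
    if (!is.null(events) && nrow(events)) {
      tg <- events$onset_sample[events$code == "target"] / attr(events, "fs")
      if (length(tg)) {
        st <- tg + cfg$event_modulation$onset
        en <- tg + cfg$event_modulation$offset
        trunc <- en > cfg$duration
        if (any(trunc))
          warning(sum(trunc), " modulation interval(s) truncated at the ",
                  "recording end")
        mod <- tibble::tibble(start = st, end = pmin(en, cfg$duration),
                              truncated = trunc)
        mod <- mod[mod$start < cfg$duration, ]
      }
    }
    mod_mask <- rep(FALSE, T)
    if (nrow(mod)) {
      for (r in seq_len(nrow(mod))) {
        a <- floor(mod$start[r] * fs) + 1L
        b <- min(ceiling(mod$end[r] * fs), T)
        if (a <= b) mod_mask[a:b] <- TRUE
      }
    }
    # coupled pairs: slave phase = master phase - lag + smooth jitter
    if (!is.null(cfg$coupled_pairs) && nrow(cfg$coupled_pairs)) {
      w <- max(1L, round(cfg$jitter_tau * fs))
      for (r in seq_len(nrow(cfg$coupled_pairs))) {
        p <- cfg$coupled_pairs[r, ]
        eps <- smooth_ma(stats::rnorm(T), w)
        eps <- eps / stats::sd(eps)
        sig <- p$kappa^(-0.5) *
          ifelse(mod_mask, cfg$event_modulation$kappa_multiplier^(-0.5), 1)
        phases[p$j + 1L, ] <- phases[p$i + 1L, ] - p$lag + eps * sig
      }
    }
    data <- cfg$amplitude * cos(phases)
    # zero-lag common source mixed into all channels
    gain <- rep_len(cfg$common_source_gain, N)
    if (any(gain != 0)) {
      src <- cfg$amplitude * cos(omega * tvec + stats::runif(1, -pi, pi) +
                                   cumsum(stats::rnorm(T, 0, cfg$drift_sd)))
      data <- data + outer(gain, rep(1, T)) * matrix(src, N, T, byrow = TRUE)
    }
    # gait-locked artifact, identical (zero-lag) on every channel: an impact
    # transient at each heel-strike plus a continuous gait-locked pedestal at
    # the gait harmonic nearest the carrier
    heel <- numeric(0)
    if (cfg$gait_period > 0 && (cfg$gait_amplitude > 0 || cfg$gait_inband > 0)) {
      heel <- seq(0, by = cfg$gait_period,
                  length.out = floor(cfg$duration / cfg$gait_period))
      if (cfg$gait_amplitude > 0) {
        tmpl <- gait_template(fs, cfg$gait_period, cfg$gait_amplitude)
        L <- length(tmpl)
        for (h in heel) {
          c0 <- round(h * fs) + 1L            # template centred on strike
          a <- c0 - L %/% 2L
          idx <- seq(a, a + L - 1L)
          ok <- idx >= 1L & idx <= T
          if (any(ok))
            data[, idx[ok]] <- data[, idx[ok]] +
              matrix(tmpl[ok], N, sum(ok), byrow = TRUE)
        }
      }
      if (cfg$gait_inband > 0) {
        f0 <- 1 / cfg$gait_period
        kstar <- max(1L, round(cfg$carrier_freq / f0))
        ped <- cfg$gait_inband * cos(2 * pi * kstar * f0 * tvec)
        data <- data + matrix(ped, N, T, byrow = TRUE)
      }
    }
    # optional fixed-latency voltage deflection after each target
    if (cfg$erp$amplitude != 0 && !is.null(events) && nrow(events)) {
      chans <- cfg$erp$channels
      if (is.null(chans)) chans <- seq_len(max(1L, N %/% 2L)) - 1L
      tg <- events$onset_sample[events$code == "target"] / attr(events, "fs")
      w0 <- cfg$erp$window[1]; w1 <- cfg$erp$window[2]
      L <- round((w1 - w0) * fs)
      shape <- sin(pi * seq_len(L) / (L + 1)) * cfg$erp$amplitude
      for (tgi in tg) {
        a <- round((tgi + w0) * fs) + 1L
        idx <- seq(a, a + L - 1L)
        ok <- idx >= 1L & idx <= T
        if (any(ok))
          data[chans + 1L, idx[ok]] <- data[chans + 1L, idx[ok]] +
            matrix(shape[ok], length(chans), sum(ok), byrow = TRUE)
      }
    }
    # grossly noisy channels, then sensor noise everywhere
    if (!is.null(cfg$bad_channels) && nrow(cfg$bad_channels)) {
      for (r in seq_len(nrow(cfg$bad_channels)))
        data[cfg$bad_channels$index[r] + 1L, ] <-
          stats::rnorm(T, 0, cfg$bad_channels$sigma[r])
    }
    data <- data + matrix(stats::rnorm(N * T, 0, cfg$noise_sd), N, T)
    heel_samples <- floor(heel * fs)
    heel_events <- if (length(heel))
      event_table(heel_samples,
                  rep_len(c("heelstrike_L", "heelstrike_R"), length(heel)),
                  fs = fs) else NULL
    truth <- structure(list(
      coupled_pairs = cfg$coupled_pairs,
      modulation = mod,
      heelstrike_onsets = heel_samples,
      heelstrike_events = heel_events,
      bad_channels = cfg$bad_channels), class = "sim_ground_truth")
    rec <- new_recording(data, fs = fs,
                         positions = default_positions(N),
                         meta = list(simulated = "true"))
    list(recording = rec, truth = truth)
  })
}

#' Default unit-disc electrode layout
#'
#' Channels are laid out on concentric rings of a unit disc, anterior at the
#' top — a stand-in for a real montage sufficient for the neighbour-based
#' quality-control rule and for topographic rendering.
#'
#' @param n_channels Channel count.
#' @return A `n_channels x 2` matrix of x/y coordinates.
#' @export
default_positions <- function(n_channels) {
  # sunflower (golden-angle) layout: roughly uniform density on the disc
  k <- seq_len(n_channels)
  r <- sqrt((k - 0.5) / n_channels)
  th <- k * pi * (3 - sqrt(5))
  cbind(x = r * cos(th), y = r * sin(th))
}
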