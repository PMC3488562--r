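test_that("instantaneous phase of quadrature tones matches theory", {
  fs <- 51.2; t <- (0:(20 * fs - 1)) / fs
  rec <- new_recording(rbind(cos(2 * pi * 4 * t), sin(2 * pi * 4 * t)),
                       fs = fs,
                       meta = list(band = c(center = 4, half_width = 2)))
  ph <- analytic_phase(rec)
  core <- seq(round(0.5 * fs), length(t) - round(0.5 * fs))
  want <- wrap_phase(2 * pi * 4 * t)
  err <- abs(wrap_phase(ph$phases[1, core] - want[core]))
  expect_lt(max(err), 0.05)
  # sine lags cosine by pi/2 everywhere
  lag <- wrap_phase(ph$phases[1, core] - ph$phases[2, core])
  expect_lt(max(abs(lag - pi / 2)), 0.05)
  expect_true(all(ph$phases > -pi & ph$phases <= pi))
})

test_that("analytic phase agrees with an independent Hilbert oracle", {
  withr::with_seed(42, {
    x <- as.numeric(stats::filter(rnorm(512), rep(1, 8) / 8,
                                  method = "convolution", sides = 2))
    x[is.na(x)] <- 0
  })
  rec <- new_recording(rbind(x, rev(x)), fs = 51.2,
                       meta = list(band = c(center = 4, half_width = 2)))
  ph <- analytic_phase(rec)
  want1 <- atan2(oracle_hilbert(x), x)
  expect_lt(max(abs(ph$phases[1, ] - want1)), 1e-9)
})

test_that("all-zero channels yield NaN phases with a warning", {
  rec <- new_recording(rbind(rep(0, 100), rnorm(100)), fs = 51.2,
                       meta = list(band = c(center = 4, half_width = 2)))
  expect_warning(ph <- analytic_phase(rec), "all-zero")
  expect_true(all(is.nan(ph$phases[1, ])))
  expect_false(anyNA(ph$phases[2, ]))
})

test_that("phase differences wrap into (-pi, pi]", {
  ph <- structure(list(phases = rbind(rep(3.0, 5), rep(-3.0, 5)), fs = 1,
                       source_meta = list()), class = "phase_set")
  d <- phase_differences(ph, make_pair_index(2))
  expect_equal(d[1, ], rep(6 - 2 * pi, 5))
  # identical phases give zero, constant offsets are preserved
  ph2 <- structure(list(phases = rbind(1:5 / 10, 1:5 / 10 - pi / 2), fs = 1,
                        source_meta = list()), class = "phase_set")
  expect_equal(phase_differences(ph2, make_pair_index(2))[1, ], rep(pi / 2, 5))
  expect_equal(wrap_phase(c(pi, -pi, 0)), c(pi, pi, 0))
})

test_that("single-window WPLI matches hand-computed values", {
  expect_identical(wpli_window(rep(pi / 2, 3)), 1)
  expect_identical(wpli_window(c(pi / 2, -pi / 2)), 0)
  expect_equal(wpli_window(c(pi / 2, pi / 2, -pi / 2)), 1 / 3)
  expect_identical(wpli_window(c(0, 0, 0)), 0)
  expect_identical(wpli_window(c(pi, pi)), 0)     # sin(pi) ~ 0: convention
  expect_error(wpli_window(numeric(0)), "empty")
  # bound: WPLI in [0, 1] for arbitrary inputs
  withr::with_seed(8, {
    for (r in 1:50) {
      v <- wpli_window(runif(25, -pi, pi))
      expect_gte(v, 0); expect_lte(v, 1)
    }
  })
})

test_that("sliding WPLI has the documented window geometry", {
  ph <- structure(list(phases = matrix(runif(2 * 49, -pi, pi), 2), fs = 51.2,
                       source_meta = list()), class = "phase_set")
  ps <- wpli_sliding(ph, win = window_spec(25, 12))
  expect_equal(ncol(ps$values), 3L)            # floor((49-25)/12)+1
  expect_equal(ps$window_centers[1], (25 - 1) / 2 / 51.2)
  expect_equal(diff(ps$window_centers), rep(12 / 51.2, 2))
  expect_error(wpli_sliding(
    structure(list(phases = matrix(0.1, 2, 10), fs = 51.2,
                   source_meta = list()), class = "phase_set")),
    "shorter")
  expect_error(window_spec(25, 26), "hop")
})

test_that("sliding WPLI and stability match brute-force recomputation", {
  withr::with_seed(33, {
    phases <- matrix(runif(6 * 200, -pi, pi), 6)
  })
  ph <- structure(list(phases = phases, fs = 51.2, source_meta = list()),
                  class = "phase_set")
  ps <- wpli_sliding(ph, win = window_spec(25, 12))
  expect_lt(max(abs(ps$values - naive_wpli_sliding(phases, 51.2, 25, 12))),
            1e-12)
  ws <- wplis(ps, cov_window = 0.5)
  expect_lt(max(abs(ws$values - naive_wplis(ps$values, 3))), 1e-12)
})

test_that("WPLI is invariant to positive channel rescaling", {
  cfg <- sim_config(n_channels = 3, duration = 20,
                    coupled_pairs = data.frame(i = 0L, j = 1L, lag = pi / 3,
                                               kappa = 2),
                    seed = 3)
  sim <- generate_recording(cfg, NULL)
  rec <- decimate_by_int(bandpass(sim$recording), 10)
  rec2 <- rec
  rec2$data <- rec2$data * c(7, 0.01, 130)
  a <- wpli_sliding(analytic_phase(rec))
  b <- wpli_sliding(analytic_phase(rec2))
  expect_lt(max(abs(a$values - b$values)), 1e-9)
})

test_that("strong coupling at quarter-cycle lag saturates WPLI", {
  cfg <- sim_config(n_channels = 3, duration = 30,
                    coupled_pairs = data.frame(i = 0L, j = 1L, lag = pi / 2,
                                               kappa = 100),
                    noise_sd = 1, seed = 12)
  sim <- generate_recording(cfg, NULL)
  rec <- decimate_by_int(bandpass(sim$recording), 10)
  ps <- wpli_sliding(analytic_phase(rec))
  vals <- ps$values[1, ]           # the coupled pair (0,1)
  expect_true(all(vals > 0.95))
})

test_that("heel-strike epoching counts windows and skips edge events", {
  ph <- structure(list(phases = matrix(runif(2 * 1024, -pi, pi), 2),
                       fs = 51.2, source_meta = list()), class = "phase_set")
  ps <- wpli_sliding(ph)
  ev <- event_table(c(0, 5120), c("heelstrike_L", "heelstrike_R"), fs = 512)
  hl <- heelstrike_locked(ps, ev, pre = 0.5, post = 0.5)
  expect_equal(hl$n_skipped, 1L)    # the strike at sample 0
  expect_equal(dim(hl$values)[2], 1L)
  # windows per epoch: centres within +-0.5 s at a 12/51.2 s step
  expect_true(dim(hl$values)[3] %in% 4:5)
  ev2 <- event_table(10, "standard", fs = 512)
  expect_error(heelstrike_locked(ps, ev2), "heel-strike")
})
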