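test_that("oddball schedules have the designed gap and target statistics", {
  ev <- generate_oddball_schedule(300, fs = 512, seed = 7)
  gaps <- diff(ev$onset_sample) / 512
  # gap = stim 0.5 s + Uniform(0.5, 1.5) s: mean 1.5, bounded [1, 2]
  expect_gt(min(gaps), 1 - 1e-3)
  expect_lt(max(gaps), 2 + 1e-3)
  expect_lt(abs(mean(gaps) - 1.5), 3 * sqrt(1 / 12) / sqrt(length(gaps)) + 0.02)
  n <- nrow(ev)
  expect_gt(n, 300 / 2 * 0.8)     # ~200 stimuli expected
  ptar <- mean(ev$code == "target")
  expect_lt(abs(ptar - 0.2), 3 * sqrt(0.2 * 0.8 / n))
  # determinism and domain checks
  expect_identical(generate_oddball_schedule(60, 512, seed = 3),
                   generate_oddball_schedule(60, 512, seed = 3))
  expect_error(generate_oddball_schedule(60, 512, p_target = 0), "p_target")
  expect_error(generate_oddball_schedule(60, 512, isi_range = c(2, 1)),
               "isi_range")
})

test_that("identical configuration and seed give bit-identical recordings", {
  cfg <- sim_config(n_channels = 4, duration = 10,
                    coupled_pairs = data.frame(i = 0L, j = 1L, lag = pi / 2,
                                               kappa = 5),
                    gait_period = 1.25, seed = 99)
  ev <- generate_oddball_schedule(10, 512, seed = 99)
  a <- generate_recording(cfg, ev)
  b <- generate_recording(cfg, ev)
  expect_identical(a$recording$data, b$recording$data)
  expect_identical(a$truth$heelstrike_onsets, b$truth$heelstrike_onsets)
})

test_that("designed lags are recovered from the instantaneous phase", {
  for (lag in c(0.7, pi / 2, 2.5)) {
    cfg <- sim_config(n_channels = 3, duration = 30,
                      coupled_pairs = data.frame(i = 0L, j = 1L, lag = lag,
                                                 kappa = 10),
                      gait_period = 0, seed = 21)
    sim <- generate_recording(cfg, NULL)
    rec <- decimate_by_int(bandpass(sim$recording), 10)
    ph <- analytic_phase(rec)
    dphi <- phase_differences(ph, make_pair_index(3))[1, ]
    circ_mean <- atan2(mean(sin(dphi)), mean(cos(dphi)))
    expect_lt(abs(atan2(sin(circ_mean - lag), cos(circ_mean - lag))), 0.1)
  }
})

test_that("heel-strikes are periodic and the impact carries the energy", {
  cfg <- sim_config(n_channels = 4, duration = 60, gait_period = 1.25,
                    gait_amplitude = 1000, seed = 7)
  sim <- generate_recording(cfg, NULL)
  hs <- sim$truth$heelstrike_onsets
  expect_length(hs, 48L)  # floor(60 / 1.25)
  expect_equal(diff(hs), rep(1.25 * 512, 47))
  expect_equal(sim$truth$heelstrike_events$code[1:2],
               c("heelstrike_L", "heelstrike_R"))
  d <- sim$recording$data
  near <- unlist(lapply(hs, function(h) (h - 25):(h + 25))) + 1
  near <- near[near >= 1 & near <= ncol(d)]
  far <- setdiff(seq_len(ncol(d)),
                 unlist(lapply(hs, function(h) (h - 90):(h + 90))) + 1)
  ratios <- apply(d, 1, function(x) var(x[near]) / var(x[far]))
  expect_true(all(ratios >= 100))
})

test_that("zero-lag common source induces near-zero phase differences", {
  cfg <- sim_config(n_channels = 4, duration = 30, coupled_pairs = NULL,
                    common_source_gain = 20, noise_sd = 1, drift_sd = 0,
                    seed = 5)
  sim <- generate_recording(cfg, NULL)
  rec <- decimate_by_int(bandpass(sim$recording), 10)
  ph <- analytic_phase(rec)
  dphi <- phase_differences(ph, make_pair_index(4))
  core <- dphi[, 100:(ncol(dphi) - 100)]
  expect_lt(max(abs(core)), 0.2)
})

test_that("modulation intervals follow targets and truncate with a warning", {
  ev <- event_table(c(1000, 2400), c("standard", "target"), fs = 512)
  cfg <- sim_config(n_channels = 3, duration = 5.5,
                    coupled_pairs = data.frame(i = 0L, j = 1L, lag = 1,
                                               kappa = 2),
                    seed = 1)
  expect_warning(sim <- generate_recording(cfg, ev), "truncated")
  mod <- sim$truth$modulation
  expect_equal(nrow(mod), 1L)
  expect_equal(mod$start, 2400 / 512 + 0.3)
  expect_equal(mod$end, 5.5)   # 2400/512 + 1.0 = 5.69 clipped to duration
  expect_true(mod$truncated)
  ev_far <- event_table(3000, "target", fs = 512)
  expect_error(generate_recording(cfg, ev_far), "past the end")
})

test_that("bad channels are overwritten with white noise of the stated sd", {
  cfg <- sim_config(n_channels = 4, duration = 20,
                    bad_channels = data.frame(index = 2L, sigma = 500),
                    seed = 11)
  sim <- generate_recording(cfg, NULL)
  sds <- apply(sim$recording$data, 1, sd)
  expect_gt(sds[3], 450)
  expect_lt(max(sds[-3]), 100)
})
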