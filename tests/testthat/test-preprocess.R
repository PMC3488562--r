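edge_trim <- function(x, fs, s = 1) x[(s * fs):(length(x) - s * fs)]

test_that("band-pass keeps the centre frequency and rejects far-out tones", {
  rec <- sine_recording(c(4, 50), fs = 512, dur = 6)
  out <- bandpass(rec, band_spec(4, 2))
  in4 <- edge_trim(rec$data[1, ], 512)
  out4 <- edge_trim(out$data[1, ], 512)
  # analytic |H| at the centre of a Butterworth band-pass is ~1; zero-phase
  # filtering squares the magnitude but leaves 1 at the centre
  expect_lt(abs(max(abs(out4)) / max(abs(in4)) - 1), 0.05)
  out50 <- edge_trim(out$data[2, ], 512)
  expect_lt(sqrt(mean(out50^2)) / sqrt(mean(edge_trim(rec$data[2, ], 512)^2)),
            0.05)
  # linearity: zero in, zero out
  z <- new_recording(matrix(0, 2, 1024), fs = 512)
  expect_equal(bandpass(z, band_spec(4, 2))$data, matrix(0, 2, 1024))
  expect_error(bandpass(rec, band_spec(250, 10)), "Nyquist")
  expect_error(band_spec(2, 3), "above 0")
})

test_that("high-pass removes DC and passes 10 Hz essentially unchanged", {
  rec <- new_recording(rbind(rep(100, 3072),
                             10 * sin(2 * pi * 10 * (0:3071) / 512)),
                       fs = 512)
  out <- highpass(rec, 1)
  expect_lt(max(abs(edge_trim(out$data[1, ], 512))), 1)
  a10 <- max(abs(edge_trim(out$data[2, ], 512)))
  expect_lt(abs(a10 / 10 - 1), 0.05)
  expect_error(highpass(rec, 512), "cutoff")
})

test_that("integer decimation keeps every factor-th sample from sample 0", {
  rec <- new_recording(rbind(0:99, 100:199), fs = 512,
                       meta = list(band = c(center = 4, half_width = 2)))
  dec <- decimate_by_int(rec, 10L)
  expect_equal(dec$data[1, ], seq(0, 90, by = 10))
  expect_equal(dec$fs, 51.2)
  expect_equal(dec$fs * 10, rec$fs)
  expect_equal(ncol(dec$data), ceiling(100 / 10))
  expect_identical(decimate_by_int(rec, 1L), rec)
  expect_error(decimate_by_int(rec, 2.5), "integer")
  rec2 <- new_recording(matrix(rnorm(200), 2), fs = 512)
  expect_warning(decimate_by_int(rec2, 10L), "band")
})

test_that("the three channel-rejection rules fire on their own pathologies", {
  fx <- qc_fixture(seed = 5)
  qc <- detect_bad_channels(highpass(fx$rec, 1), neighbor_radius = 0.4)
  expect_true(qc$rule_sd[qc$channel == 3])          # sigma 2000 > 1000
  expect_true(qc$rule_kurtosis[qc$channel == 11])   # Laplacian tails
  expect_true(qc$rule_corr[qc$channel == 20])       # decorrelated
  expect_true(all(fx$bad %in% qc$channel[qc$rejected]))
  expect_lte(sum(qc$rejected & !qc$channel %in% fx$bad), 1L)
  expect_gt(qc$low_corr_frac[qc$channel == 20], 0.5)
  # rejected <=> at least one rule fired
  expect_equal(qc$rejected, qc$rule_sd | qc$rule_kurtosis | qc$rule_corr)
})

test_that("bad-channel detection is permutation-equivariant", {
  fx <- qc_fixture(seed = 17)
  rec <- highpass(fx$rec, 1)
  perm <- withr::with_seed(1, sample(32))
  rec_p <- new_recording(rec$data[perm, ], fs = rec$fs,
                         labels = rec$labels[perm],
                         positions = rec$positions[perm, ])
  qc <- detect_bad_channels(rec, neighbor_radius = 0.4)
  qc_p <- detect_bad_channels(rec_p, neighbor_radius = 0.4)
  expect_equal(qc_p$rejected, qc$rejected[perm])
  expect_equal(qc_p$sd, qc$sd[perm])
  expect_equal(qc_p$kurtosis, qc$kurtosis[perm])
})

test_that("correlation rule without positions is a configuration error", {
  rec <- new_recording(matrix(rnorm(4 * 1024), 4), fs = 512)
  expect_error(detect_bad_channels(rec), "positions")
  expect_s3_class(detect_bad_channels(rec, rules = c("sd", "kurtosis")),
                  "channel_qc_report")
})

test_that("average re-reference zeroes the channel mean at every sample", {
  rec <- new_recording(matrix(rnorm(8 * 1000), 8), fs = 512)
  out <- rereference_average(rec)
  expect_lt(max(abs(colMeans(out$data))), 1e-12)
  # two opposite constant channels are already average-referenced
  r2 <- new_recording(rbind(rep(1, 10), rep(-1, 10)), fs = 10)
  expect_equal(rereference_average(r2)$data, r2$data)
  # identical channels cancel to zero
  r3 <- new_recording(matrix(5, 3, 10), fs = 10)
  expect_equal(rereference_average(r3)$data, matrix(0, 3, 10))
  # excluded channels are dropped
  out2 <- rereference_average(rec, exclude = c(0L, 5L))
  expect_equal(nrow(out2$data), 6L)
  expect_error(rereference_average(rec, exclude = 0:7), "at least 2")
})
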