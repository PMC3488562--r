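mk_series <- function(values, step = 12 / 51.2, kind = "wpli") {
  values <- matrix(values, nrow = 1)
  pi2 <- make_pair_index(2)
  new_pair_series(values, window_centers = (seq_len(ncol(values)) - 1) * step,
                  window_len = 25L, hop = 12L, fs = 51.2, pair_index = pi2,
                  kind = kind)
}

test_that("stability is the trailing coefficient of variation", {
  # constant WPLI: perfectly stable
  ws <- wplis(mk_series(rep(0.5, 6)))
  expect_equal(as.numeric(ws$values), rep(0, 4))
  # two-point closed form: sd = |a-b|/sqrt(2)
  ws2 <- wplis(mk_series(c(0.4, 0.6, 0.4)), cov_window = 0.4)
  expect_equal(ws2$values[1, 1], (0.2 / sqrt(2)) / 0.5, tolerance = 1e-12)
  # all-zero windows use the zero convention
  expect_equal(as.numeric(wplis(mk_series(rep(0, 5)))$values), rep(0, 3))
  # timestamps sit at the centre of the covered span
  s <- mk_series(runif(8))
  ws3 <- wplis(s)
  expect_equal(ws3$window_centers,
               s$window_centers[3:8] - 12 / 51.2)
  expect_error(wplis(mk_series(c(0.1, 0.2)), cov_window = 0.1), "at least 2")
  expect_error(wplis(wplis(mk_series(runif(8)))), "wpli")
})

test_that("stability is scale-free and zero iff the window is constant", {
  withr::with_seed(4, v <- runif(20, 0.2, 0.9))
  a <- wplis(mk_series(v))
  b <- wplis(mk_series(v * 0.37))
  expect_equal(a$values, b$values, tolerance = 1e-12)
  expect_true(all(a$values >= 0))
  const <- wplis(mk_series(rep(0.73, 10)))
  expect_true(all(const$values == 0))
  expect_true(all(a$values > 0))
})

test_that("event-locked epochs share a time axis and count skips", {
  withr::with_seed(9, s <- mk_series(runif(300)))
  fs_ev <- 512
  step <- 12 / 51.2
  # 10 events: 2 too close to the series edges
  on <- c(1, round(c(5, 10, 15, 20, 25, 30, 35, 40) / step) * 120,
          300 * 120 - 60)
  ev <- event_table(sort(on), rep("target", 10), fs = fs_ev)
  ep <- epoch_lock(s, ev, "target", pre = 0.5, post = 1.0)
  expect_equal(dim(ep$values)[2] + ep$n_skipped, 10L)
  expect_equal(ep$n_skipped, 2L)
  expect_equal(ep$rel_times, seq(-2, 4) * step)
  # a constant series gives identical epochs
  sc <- mk_series(rep(0.4, 300))
  epc <- epoch_lock(sc, ev, "target", pre = 0.5, post = 1.0)
  expect_true(all(apply(epc$values, 2, function(m) all(m == 0.4))))
  expect_error(epoch_lock(s, ev, "button"), "button")
})

test_that("grand mean equals an explicit two-stage averaging oracle", {
  withr::with_seed(11, {
    eps <- lapply(1:8, function(s) {
      arr <- array(runif(3 * 4 * 7), c(3, 4, 7))
      structure(list(values = arr, rel_times = seq(-2, 4) * 0.2,
                     event_code = "target", n_skipped = 0L,
                     pair_index = make_pair_index(3), kind = "wplis"),
                class = "epoch_set")
    })
  })
  gm <- grand_mean(eps)
  curves <- sapply(eps, function(e) {
    out <- numeric(7)
    for (w in 1:7) {
      acc <- 0
      for (p in 1:3) for (ei in 1:4) acc <- acc + e$values[p, ei, w]
      out[w] <- acc / 12
    }
    out
  })
  expect_equal(gm$mean, rowMeans(curves), tolerance = 1e-12)
  expect_equal(gm$se, apply(curves, 1, sd) / sqrt(8), tolerance = 1e-12)
  # identical subjects have zero se; mirrored subjects have zero mean
  gm2 <- grand_mean(list(eps[[1]], eps[[1]], eps[[1]], eps[[1]]))
  expect_true(all(gm2$se == 0))
  neg <- eps[[1]]; neg$values <- -neg$values; neg$kind <- "wpli"
  expect_equal(grand_mean(list(eps[[1]], neg))$mean, rep(0, 7),
               tolerance = 1e-12)
  bad <- eps[[2]]; bad$rel_times <- bad$rel_times + 1
  expect_error(grand_mean(list(eps[[1]], bad)), "mismatched")
})

test_that("deflection statistics match closed-form cases", {
  rt <- seq(-0.5, 1.5, by = 0.25)
  flat <- tibble::tibble(rel_time = rt, mean = rep(0.2, length(rt)),
                         se = rep(0.01, length(rt)))
  st <- deflection_stats(flat)
  expect_equal(st$pct_change, 0)
  expect_equal(st$z, 0)
  expect_equal(st$p, 1)
  dip <- flat
  dip$mean[rt == 0.75] <- 0.18
  st2 <- deflection_stats(dip)
  expect_equal(st2$baseline_mean, 0.2)
  expect_equal(st2$min_value, 0.18)
  expect_equal(st2$min_time, 0.75)
  expect_equal(st2$pct_change, 10)
  # z and two-sided normal tail: baseline .10, min .096, se .001 -> z 4
  g <- tibble::tibble(rel_time = rt, mean = c(rep(0.1, 2), rep(0.1, 6), 0.096),
                      se = rep(0.001, 9))
  st3 <- deflection_stats(g)
  expect_equal(st3$z, 4)
  expect_equal(st3$p, 2 * pnorm(-4))
  expect_equal(st3$p, 6.33e-5, tolerance = 1e-2)
  expect_error(deflection_stats(flat[rt >= -0.1, ]), "cover")
})

test_that("rows order by correlation to the mean, ties and zeros first", {
  m <- rbind(sin(1:50), sin(1:50), -sin(1:50))
  expect_equal(sort_by_corr_to_mean(m)[1], 3L)
  # all-identical rows keep original order
  expect_equal(sort_by_corr_to_mean(matrix(1:10, 4, 10, byrow = TRUE)), 1:4)
  # random matrix matches a direct oracle
  withr::with_seed(6, m2 <- matrix(rnorm(20 * 50), 20))
  mu <- colMeans(m2)
  cc <- apply(m2, 1, function(r)
    sum((r - mean(r)) * (mu - mean(mu))) / (sd(r) * sd(mu) * 49))
  expect_equal(sort_by_corr_to_mean(m2), order(cc))
  # zero-variance rows get correlation 0 and sort before everything
  m3 <- rbind(rep(1, 10), sin(1:10), -sin(1:10))
  expect_equal(sort_by_corr_to_mean(m3)[1], 1L)
  expect_error(sort_by_corr_to_mean(m3[1, , drop = FALSE]), "2 rows")
})

test_that("voltage epochs cut at full rate and normalise per channel", {
  fs <- 512
  t <- (0:(20 * fs - 1)) / fs
  rec <- new_recording(rbind(30 * sin(2 * pi * 4 * t), rnorm(length(t))),
                       fs = fs)
  ev <- event_table(round(c(5, 10, 15) * fs), rep("target", 3), fs = fs)
  er <- voltage_erp(rec, ev, "target", pre = 0.5, post = 1, normalize = TRUE)
  expect_equal(dim(er$values), c(2L, 3L, round(1.5 * fs) + 1L))
  # a constant-amplitude sinusoid normalises to ~ +-(pi/2) peak (1/mean|x|)
  expect_lt(max(abs(er$values[1, , ])), pi / 2 + 0.1)
  expect_gt(max(er$values[1, , ]), 1.2)
  expect_warning(voltage_erp(rec, ev, "button"), "no events")
  er2 <- voltage_erp(rec, ev, "target", normalize = FALSE)
  expect_equal(max(abs(er2$values[1, , ])), 30, tolerance = 0.01)
})
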