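# WPLI stability (trailing-window coefficient of variation), event-locked
# epoching, grand means across subjects, and deflection statistics.

#' WPLI stability (trailing coefficient of variation)
#'
#' For each pair and each WPLI window index `tau` with a full trailing
#' window, computes the coefficient of variation (sample SD / mean) of the
#' WPLI values whose centres lie in `(t_tau - cov_window, t_tau]`. The window
#' is trailing (causal), so the statistic is computable on-line. Low values
#' mean stable, uniform connectivity; the event-locked *decrease* in this
#' statistic is the pipeline's headline readout. With the default geometry
#' (hop 12 at 51.2 Hz) each value summarises 3 WPLI windows.
#'
#' @param series A `pair_series` of kind `"wpli"`.
#' @param cov_window Trailing window length in seconds (default 0.5).
#' @return A `pair_series` of kind `"wplis"`, one value per `tau` with a full
#'   trailing window. Each value is timestamped at the centre of the span it
#'   summarises (the mean of the contributing WPLI window centres); being
#'   causal, it becomes available on-line half a `cov_window` later. A
#'   non-positive windowed mean (only possible for an all-zero window) yields
#'   0 by convention.
#' @export
wplis <- function(series, cov_window = 0.5) {
  stopifnot(inherits(series, "pair_series"))
  if (series$kind != "wpli") stop_domain("wplis() expects a wpli pair_series")
  step <- series$hop / series$fs
  k <- sum(seq(0, by = step, length.out = ncol(series$values)) <
             cov_window - 1e-12)
  if (k < 2L)
    stop_domain("cov_window must cover at least 2 WPLI values ",
                "(got ", k, " at a step of ", signif(step, 4), " s)")
  nw <- ncol(series$values) - k + 1L
  if (nw < 1L) stop_domain("series shorter than one stability window")
  v <- series$values
  cs <- cbind(0, t(apply(v, 1L, cumsum)))
  cq <- cbind(0, t(apply(v^2, 1L, cumsum)))
  idx <- seq_len(nw)
  sums <- cs[, idx + k, drop = FALSE] - cs[, idx, drop = FALSE]
  sqs <- cq[, idx + k, drop = FALSE] - cq[, idx, drop = FALSE]
  mu <- sums / k
  var <- pmax(sqs / k - mu^2, 0) * k / (k - 1)   # sample (n-1) variance
  # clamp cancellation noise so constant windows give exactly 0
  var[var < 1e-12 * mu^2] <- 0
  out <- ifelse(mu <= 0, 0, sqrt(var) / mu)
  # each value is timestamped at the centre of the span it covers (the mean
  # of the contributing WPLI window centres); it becomes *available* on-line
  # at the trailing edge, (k-1)/2 steps later
  centers <- series$window_centers[k:ncol(series$values)] - (k - 1) / 2 * step
  new_pair_series(out, centers,
                  series$window_len, series$hop, series$fs,
                  series$pair_index, kind = "wplis")
}

#' Event-locked epochs of a pair series
#'
#' Cuts, for every event of the given code(s), the consecutive run of series
#' windows whose centres fall within `[onset - pre, onset + post]`. Runs are
#' aligned on the window nearest each onset so that all epochs share one
#' relative-time axis; events too close to the edges are skipped and counted.
#'
#' @param series A `pair_series`.
#' @param events An [event_table()].
#' @param code Event code(s) to lock to (e.g. `"target"`).
#' @param pre,post Epoch extent in seconds before/after the event.
#' @return A list of class `epoch_set`: `values` (pairs x epochs x
#'   relative-windows array), `rel_times` (s), `event_code`, `n_skipped`,
#'   `pair_index`, `kind`.
#' @export
epoch_lock <- function(series, events, code, pre = 0.5, post = 1.0) {
  stopifnot(inherits(series, "pair_series"))
  ev <- events[events$code %in% code, ]
  if (!nrow(ev)) stop_domain("no events with code ",
                             paste(code, collapse = "/"))
  t_ev <- ev$onset_sample / attr(events, "fs")
  step <- series$hop / series$fs
  n_pre <- floor(pre / step + 1e-9)
  n_post <- floor(post / step + 1e-9)
  rel_times <- seq(-n_pre, n_post) * step
  centers <- series$window_centers
  nw <- length(centers)
  keep <- list(); skipped <- 0L
  for (te in t_ev) {
    i0 <- which.min(abs(centers - te))
    if (i0 - n_pre < 1L || i0 + n_post > nw) { skipped <- skipped + 1L; next }
    keep[[length(keep) + 1L]] <- (i0 - n_pre):(i0 + n_post)
  }
  if (!length(keep))
    stop_domain("no events of code ", paste(code, collapse = "/"),
                " with full pre/post context")
  np <- nrow(series$values)
  arr <- array(NA_real_, c(np, length(keep), n_pre + n_post + 1L))
  for (e in seq_along(keep)) arr[, e, ] <- series$values[, keep[[e]]]
  structure(list(values = arr, rel_times = rel_times,
                 event_code = paste(code, collapse = "/"),
                 n_skipped = skipped, pair_index = series$pair_index,
                 kind = series$kind),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<epoch_set:%s> %d pairs x %d epochs x %d windows, locked to %s (%d skipped)\n",
    x$kind, d[1], d[2], d[3], x$event_code, x$n_skipped))
  invisible(x)
}

#' Tidy an epoch set
#' @param x An `epoch_set`.
#' @param ... Unused.
#' @return Tibble with columns `pair`, `epoch`, `rel_time`, `value`.
#' @export
tidy.epoch_set <- function(x, ...) {
  d <- dim(x$values)
  tibble::tibble(pair = rep(seq_len(d[1]), times = d[2] * d[3]),
                 epoch = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
                 rel_time = rep(x$rel_times, each = d[1] * d[2]),
                 value = as.numeric(x$values))
}

#' Mean epoch response per pair
#'
#' Averages an epoch set over epochs, giving the pairs x relative-windows
#' matrix used for sorting, plotting, and the principal-component topography.
#'
#' @param epochs An `epoch_set`.
#' @return Matrix pairs x relative-windows with `rel_times` attribute.
#' @export
epoch_pair_mean <- function(epochs) {
  m <- apply(epochs$values, c(1, 3), mean)
  attr(m, "rel_times") <- epochs$rel_times
  m
}

#' Grand mean and standard error across subjects
#'
#' First averages, within each subject, over pairs and epochs to one curve;
#' then averages across subjects. The spread is the standard error across
#' subjects (SD / sqrt(n)).
#'
#' @param epochs_by_subject List of `epoch_set`s sharing `rel_times`.
#' @return A tibble of class `grand_mean` with columns `rel_time`, `mean`,
#'   `se`, and attribute `n_subjects`.
#' @export
grand_mean <- function(epochs_by_subject) {
  stopifnot(length(epochs_by_subject) >= 1L)
  rt <- epochs_by_subject[[1]]$rel_times
  for (e in epochs_by_subject)
    if (!isTRUE(all.equal(e$rel_times, rt)))
      stop_domain("epoch sets have mismatched relative-time axes")
  curves <- vapply(epochs_by_subject,
                   function(e) apply(e$values, 3L, mean),
                   numeric(length(rt)))
  curves <- matrix(curves, nrow = length(rt))
  n <- ncol(curves)
  out <- tibble::tibble(
    rel_time = rt,
    mean = rowMeans(curves),
    se = if (n > 1) apply(curves, 1L, stats::sd) / sqrt(n) else rep(0, length(rt))
  )
  attr(out, "n_subjects") <- n
  class(out) <- c("grand_mean", class(out))
  out
}

#' Deflection statistics of an event-locked curve
#'
#' Quantifies the post-event deflection of a grand-mean curve: the baseline is
#' the curve mean over `[-baseline_span, 0)`; the minimum (value and time) is
#' taken over `(0, +search_span]`; the percent change is
#' `100 (baseline - min) / baseline`; the z-score divides the drop by the
#' standard error at the minimum's time bin, and p-values are standard-normal
#' tails (two-sided headline, one-sided also reported).
#'
#' @param gm A [grand_mean()] tibble, or anything with columns
#'   `rel_time`, `mean`, `se`.
#' @param baseline_span Seconds before the event to average (default 0.5).
#' @param search_span Seconds after the event to search (default 1.5).
#' @return A one-row tibble of class `deflection_stats`: `baseline_mean`,
#'   `min_value`, `min_time`, `pct_change`, `se`, `z`, `p`
#'   (two-sided), `p_one_sided`, `n_subjects`.
#' @export
deflection_stats <- function(gm, baseline_span = 0.5, search_span = 1.5) {
  rt <- gm$rel_time
  step <- max(diff(rt))
  # rel_times are window-aligned, so "covering" a span means reaching within
  # one window step of its edge
  if (min(rt) > -baseline_span + step || max(rt) < search_span - step)
    stop_domain("rel_times do not cover the baseline/search spans")
  base_idx <- which(rt >= -baseline_span - 1e-9 & rt < 0)
  post_idx <- which(rt > 0 & rt <= search_span + 1e-9)
  if (!length(base_idx) || !length(post_idx))
    stop_domain("empty baseline or search region")
  baseline <- mean(gm$mean[base_idx])
  im <- post_idx[which.min(gm$mean[post_idx])]
  min_value <- gm$mean[im]
  min_time <- rt[im]
  se_min <- gm$se[im]
  if (baseline <= 0) {
    warning("non-positive baseline mean; percent change undefined")
    pct <- NA_real_
  } else {
    pct <- 100 * (baseline - min_value) / baseline
  }
  z <- if (se_min > 0) (baseline - min_value) / se_min
       else if (baseline == min_value) 0 else sign(baseline - min_value) * Inf
  p2 <- if (is.finite(z)) 2 * stats::pnorm(-abs(z)) else 0
  p2 <- min(p2, 1)
  out <- tibble::tibble(baseline_mean = baseline, min_value = min_value,
                        min_time = min_time, pct_change = pct, se = se_min,
                        z = z, p = p2,
                        p_one_sided = if (is.finite(z)) stats::pnorm(-z) else 0,
                        n_subjects = attr(gm, "n_subjects") %||% NA_integer_)
  class(out) <- c("deflection_stats", class(out))
  out
}

#' Order rows by correlation to their mean
#'
#' Computes each row's Pearson correlation with the across-row mean and
#' returns the row order, ascending, so the most representative rows plot at
#' the bottom of a raster. Zero-variance rows get correlation 0 and are
#' placed first; ties break by original index.
#'
#' @param m Numeric matrix, rows x time (>= 2 rows, >= 3 time points).
#' @return Integer vector of row indices (a permutation of `1:nrow(m)`).
#' @export
sort_by_corr_to_mean <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 2L) stop_domain("need at least 2 rows to sort")
  if (ncol(m) < 3L) stop_domain("need at least 3 time points")
  mu <- colMeans(m)
  sds <- apply(m, 1L, stats::sd)
  zv <- sds == 0 | stats::sd(mu) == 0
  cc <- rep(0, nrow(m))
  if (any(!zv))
    cc[!zv] <- suppressWarnings(as.numeric(stats::cor(t(m[!zv, , drop = FALSE]),
                                                      mu)))
  cc[is.na(cc)] <- 0
  order(!zv & TRUE, cc, seq_len(nrow(m)))
}

#' Event-locked voltage epochs (conventional ERP path)
#'
#' Cuts raw-voltage epochs at the full sampling rate around events of the
#' given code — the conventional event-related-potential analysis the
#' phase-lag pipeline is contrasted against. With `normalize = TRUE` each
#' channel is divided by its mean absolute voltage over the whole session.
#'
#' @param rec An `eeg_recording` (typically high-passed, full rate).
#' @param events An [event_table()].
#' @param code Event code(s) to lock to.
#' @param pre,post Epoch extent in seconds.
#' @param normalize Scale each channel by its session mean absolute voltage.
#' @return A list of class `erp_set`: `values` (channels x epochs x samples),
#'   `rel_times`, `channel_mean` (channels x samples matrix of the mean
#'   epoch), `n_skipped`. If no events match, an empty set with a warning.
#' @export
voltage_erp <- function(rec, events, code = "target", pre = 0.5, post = 1.0,
                        normalize = TRUE) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  data <- rec$data
  if (normalize) {
    scl <- rowMeans(abs(data))
    scl[scl == 0] <- 1
    data <- data / scl
  }
  ev <- events[events$code %in% code, ]
  n_pre <- round(pre * fs); n_post <- round(post * fs)
  rel_times <- seq(-n_pre, n_post) / fs
  if (!nrow(ev)) {
    warning("no events with code ", paste(code, collapse = "/"))
    return(structure(list(values = array(NA_real_,
                                         c(nrow(data), 0, n_pre + n_post + 1)),
                          rel_times = rel_times,
                          channel_mean = NULL, n_skipped = 0L),
                     class = "erp_set"))
  }
  ev_fs <- attr(events, "fs")
  onset_here <- round(ev$onset_sample / ev_fs * fs)  # 0-based at rec rate
  keep <- list(); skipped <- 0L
  for (o in onset_here) {
    idx <- (o - n_pre):(o + n_post) + 1L
    if (idx[1] < 1L || idx[length(idx)] > ncol(data)) {
      skipped <- skipped + 1L; next
    }
    keep[[length(keep) + 1L]] <- idx
  }
  if (!length(keep)) stop_domain("no events with full epoch context")
  arr <- array(NA_real_, c(nrow(data), length(keep), n_pre + n_post + 1L))
  for (e in seq_along(keep)) arr[, e, ] <- data[, keep[[e]]]
  structure(list(values = arr, rel_times = rel_times,
                 channel_mean = apply(arr, c(1, 3), mean),
                 n_skipped = skipped),
            class = "erp_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
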