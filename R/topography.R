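# Principal-component analysis of the event-locked pair response and the
# cumulative-positive-loading scalp topography.

#' First principal component of the pair response
#'
#' Treats channel pairs as variables and the time points of the epoch-mean
#' response as observations: after centring each pair's time course, the
#' leading eigenvector of the pair-by-pair covariance gives one loading per
#' pair, and the projection gives the PC1 time course. The eigenvector sign
#' is fixed so the time course's dominant extremum is negative — a
#' stabilisation dip then loads positively.
#'
#' @param epoch_mean Numeric matrix, pairs x relative-windows (e.g. from
#'   [epoch_pair_mean()]); needs >= 2 pairs and >= 2 time points.
#' @param scale Use correlation instead of covariance scaling
#'   (default `FALSE`).
#' @return A list of class `pair_pca`: `loadings` (unit-norm, one per pair),
#'   `explained_fraction`, `component_curve`, `rel_times` (if present on the
#'   input), `degenerate` flag.
#' @export
first_pc <- function(epoch_mean, scale = FALSE) {
  m <- as.matrix(epoch_mean)
  if (nrow(m) < 2L || ncol(m) < 2L)
    stop_domain("need >= 2 pairs and >= 2 time points")
  x <- m - rowMeans(m)                     # centre each pair over time
  degenerate <- FALSE
  if (all(abs(x) < .Machine$double.eps * 100)) {
    warning("zero-variance input; principal component is degenerate")
    degenerate <- TRUE
    load <- rep(1 / sqrt(nrow(m)), nrow(m))
    return(structure(list(loadings = load, explained_fraction = NA_real_,
                          component_curve = rep(0, ncol(m)),
                          rel_times = attr(epoch_mean, "rel_times"),
                          degenerate = TRUE),
                     class = "pair_pca"))
  }
  if (scale) {
    sds <- apply(x, 1L, stats::sd)
    sds[sds == 0] <- 1
    x <- x / sds
  }
  sv <- svd(t(x))                          # observations = time points
  load <- sv$v[, 1L]
  curve <- t(x) %*% load
  if (max(curve) > -min(curve)) {          # dip convention
    load <- -load
    curve <- -curve
  }
  structure(list(loadings = as.numeric(load),
                 explained_fraction = sv$d[1L]^2 / sum(sv$d^2),
                 component_curve = as.numeric(curve),
                 rel_times = attr(epoch_mean, "rel_times"),
                 degenerate = degenerate),
            class = "pair_pca")
}

#' @export
print.pair_pca <- function(x, ...) {
  cat(sprintf("<pair_pca> %d pair loadings, PC1 explains %.1f%% of variance\n",
              length(x$loadings), 100 * x$explained_fraction))
  invisible(x)
}

#' Tidy pair-PCA loadings
#' @param x A `pair_pca`.
#' @param pairs Optional [make_pair_index()] to attach channel indices.
#' @param ... Unused.
#' @return Tibble with columns `pair`, `loading` (plus `i`, `j` when `pairs`
#'   is given).
#' @export
tidy.pair_pca <- function(x, pairs = NULL, ...) {
  out <- tibble::tibble(pair = seq_along(x$loadings), loading = x$loadings)
  if (!is.null(pairs)) {
    out$i <- pairs$i
    out$j <- pairs$j
  }
  out
}

#' One-row PCA summary
#' @param x A `pair_pca`.
#' @param ... Unused.
#' @return Tibble with `n_pairs`, `explained_fraction`, `degenerate`.
#' @export
glance.pair_pca <- function(x, ...) {
  tibble::tibble(n_pairs = length(x$loadings),
                 explained_fraction = x$explained_fraction,
                 degenerate = x$degenerate)
}

#' Cumulative positive PC loading per channel
#'
#' For each channel, sums the positive PC1 loadings of every pair containing
#' it (negative loadings contribute nothing). Channels participating most
#' strongly and most often in the event-locked component get the highest
#' cumulative loading — the quantity rendered on the scalp map.
#'
#' @param pca A [first_pc()] result.
#' @param pairs The [make_pair_index()] the loadings are ordered by.
#' @return A tibble of class `loading_map` with columns `channel` (0-based)
#'   and `cum_loading` (>= 0).
#' @export
cumulative_loading <- function(pca, pairs) {
  if (length(pca$loadings) != nrow(pairs))
    stop_domain("loading count (", length(pca$loadings),
                ") != pair count (", nrow(pairs), ")")
  n <- attr(pairs, "n_channels")
  pos <- pmax(pca$loadings, 0)
  cum <- numeric(n)
  for (r in seq_len(nrow(pairs))) {
    cum[pairs$i[r] + 1L] <- cum[pairs$i[r] + 1L] + pos[r]
    cum[pairs$j[r] + 1L] <- cum[pairs$j[r] + 1L] + pos[r]
  }
  out <- tibble::tibble(channel = seq_len(n) - 1L, cum_loading = cum)
  class(out) <- c("loading_map", class(out))
  out
}

#' Render a scalp topography of cumulative loadings
#'
#' Interpolates per-channel cumulative loadings over the unit disc (inverse
#' distance weighting), draws a head outline, and marks electrodes. The
#' numeric per-channel values are also written as TSV when `values_path` is
#' given, so the map is testable without parsing pixels.
#'
#' @param map A [cumulative_loading()] tibble.
#' @param positions Channels x 2 matrix of scalp coordinates (unit disc).
#' @param out Optional image path (written via [ggplot2::ggsave()]).
#' @param values_path Optional TSV path for the per-channel values.
#' @param grid_n Interpolation grid resolution (default 67).
#' @return The ggplot object, invisibly when `out` is given.
#' @export
render_topomap <- function(map, positions, out = NULL, values_path = NULL,
                           grid_n = 67L) {
  if (is.null(positions)) stop("positions are required to render a topomap")
  positions <- as.matrix(positions)
  if (nrow(positions) != nrow(map))
    stop_domain("positions/channel count mismatch")
  if (!is.null(values_path)) {
    df <- data.frame(channel = map$channel, x = positions[, 1],
                     y = positions[, 2], cum_loading = map$cum_loading)
    utils::write.table(df, values_path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  gx <- seq(-1.05, 1.05, length.out = grid_n)
  grid <- expand.grid(x = gx, y = gx)
  inside <- grid$x^2 + grid$y^2 <= 1.05^2
  z <- rep(NA_real_, nrow(grid))
  # inverse-distance-weighted interpolation (power 2)
  gi <- which(inside)
  d2 <- outer(grid$x[gi], positions[, 1], "-")^2 +
    outer(grid$y[gi], positions[, 2], "-")^2
  w <- 1 / pmax(d2, 1e-9)
  z[gi] <- (w %*% map$cum_loading) / rowSums(w)
  grid$loading <- z
  theta <- seq(0, 2 * pi, length.out = 181)
  headline <- data.frame(x = cos(theta), y = sin(theta))
  elec <- data.frame(x = positions[, 1], y = positions[, 2])
  p <- ggplot2::ggplot(grid[inside, ],
                       ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$loading)) +
    ggplot2::scale_fill_viridis_c(option = "inferno",
                                  name = "cumulative\nPC1 loading") +
    ggplot2::geom_path(data = headline, linewidth = 0.6) +
    ggplot2::geom_point(data = elec, size = 0.6, colour = "grey30") +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
  if (!is.null(out)) {
    ggplot2::ggsave(out, p, width = 5, height = 4, dpi = 150)
    return(invisible(p))
  }
  p
}
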