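# ggplot2 views of the package's result types.

#' Raster view of a pair series
#'
#' Pairs on the y axis (sorted by correlation to the mean response, most
#' representative at the bottom), window-centre time on the x axis.
#'
#' @param object A `pair_series` or `epoch_set` (epochs are averaged first).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pair_series <- function(object, ...) {
  ord <- sort_by_corr_to_mean(object$values)
  df <- tidy(object)
  rank_map <- match(seq_len(nrow(object$values)), ord)
  np <- nrow(object$values)
  df$row <- rank_map[rep(seq_len(np), length(object$window_centers))]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = object$kind) +
    ggplot2::labs(x = "time (s)", y = "channel pair (sorted)") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.pair_series
#' @export
autoplot.epoch_set <- function(object, ...) {
  m <- epoch_pair_mean(object)
  ord <- sort_by_corr_to_mean(m)
  df <- expand.grid(pair = seq_len(nrow(m)), rel_time = object$rel_times)
  df$value <- as.numeric(m)
  df$row <- match(df$pair, ord)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rel_time, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "white") +
    ggplot2::scale_fill_viridis_c(name = object$kind) +
    ggplot2::labs(x = sprintf("time relative to %s (s)", object$event_code),
                  y = "channel pair (sorted)") +
    ggplot2::theme_minimal()
}

#' Grand-mean curve with standard-error ribbon
#'
#' @param object A [grand_mean()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.grand_mean <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$rel_time, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$se,
                                      ymax = .data$mean + .data$se),
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "time relative to event (s)", y = "grand mean") +
    ggplot2::theme_minimal()
}
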