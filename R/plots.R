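# ggplot2 displays for time courses, epoch responses and statistical maps.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an ROI time course against the stimulation paradigm
#'
#' @param series Per-volume ROI means.
#' @param paradigm The run's `paradigm`.
#' @param title Plot title.
#' @return A ggplot object.
#' @export
plot_timecourse <- function(series, paradigm, title = "ROI mean signal") {
  df <- tibble::tibble(time_s = paradigm$volume_times_s[seq_along(series)],
                       signal = series)
  blocks <- tibble::tibble(xmin = paradigm$onsets_s,
                           xmax = paradigm$onsets_s + paradigm$odor_s)
  blocks <- blocks[blocks$xmin <= max(df$time_s), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$signal)) +
    ggplot2::geom_rect(data = blocks,
                       ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                                    ymin = -Inf, ymax = Inf),
                       inherit.aes = FALSE, fill = "red", alpha = 0.15) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::labs(x = "time (s)", y = "mean intensity (a.u.)",
                  title = title) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.epoch_response <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = .data$rel_s, y = .data$pct)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, color = "grey50") +
    ggplot2::geom_vline(xintercept = 0, linetype = 3, color = "red") +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::labs(x = "time from odor onset (s)",
                  y = "signal change (%)",
                  title = sprintf("Epoch-averaged response (%d epochs, peak %.1f%%)",
                                  object$n_epochs, object$peak_pct)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.activation_map <- function(object, underlay = NULL, ...) {
  d <- dim(object$stat)
  df <- tibble::tibble(
    x = rep(seq_len(d[1]), d[2]), y = rep(seq_len(d[2]), each = d[1]),
    stat = as.vector(object$stat),
    supra = as.vector(object$mask_supra))
  df$stat[!df$supra] <- NA
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y))
  if (!is.null(underlay)) {
    df$under <- as.vector(underlay)
    p <- p + ggplot2::geom_raster(data = df,
                                  ggplot2::aes(fill = NULL, alpha = .data$under),
                                  fill = "grey20", show.legend = FALSE)
  }
  p + ggplot2::geom_raster(data = df[!is.na(df$stat), ],
                           ggplot2::aes(fill = .data$stat)) +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "grey90",
                                  high = "red", name = object$stat_type) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("%s map, p < %g (%s)", object$stat_type,
                                  object$p_threshold, object$correction)) +
    ggplot2::theme_void()
}

#' Plot an image matrix
#' @param img Matrix image.
#' @param title Plot title.
#' @return A ggplot object.
#' @export
plot_image <- function(img, title = NULL) {
  d <- dim(img)
  df <- tibble::tibble(x = rep(seq_len(d[1]), d[2]),
                       y = rep(seq_len(d[2]), each = d[1]),
                       value = as.vector(img))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 name = NULL) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = title) +
    ggplot2::theme_void()
}
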