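# ggplot2 visualisation helpers for the main result types.

#' Plot a volume slice as a grey-scale raster
#'
#' @param object A [volume_image()].
#' @param slice Slice index.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.volume_image <- function(object, slice = 1L, ...) {
  vv <- object$values[, , slice]
  d <- dim(vv)
  df <- data.frame(x = rep(seq_len(d[1]), d[2]) * object$voxel_size,
                   y = rep(seq_len(d[2]), each = d[1]) * object$voxel_size,
                   value = as.numeric(vv))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)",
                  fill = object$semantics) +
    ggplot2::theme_minimal()
}

#' Plot per-vessel waterfront tracks with the cohort band
#'
#' Reproduces the standard front-progression chart: per-vessel `h(t)` with
#' threshold-sweep error bars, the cohort median in dark grey and the
#' +/- 1 sd band in light grey.
#'
#' @param object A `vessel_tracks` object from [track_vessels()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vessel_tracks <- function(object, ...) {
  tr <- object$tracks
  co <- object$cohort
  ggplot2::ggplot() +
    ggplot2::geom_ribbon(data = co,
                         ggplot2::aes(x = .data$t, ymin = .data$median_h - .data$sd_h,
                                      ymax = .data$median_h + .data$sd_h),
                         fill = "grey80") +
    ggplot2::geom_line(data = co, ggplot2::aes(x = .data$t, y = .data$median_h),
                       colour = "grey30", linewidth = 1) +
    ggplot2::geom_errorbar(data = tr,
                           ggplot2::aes(x = .data$t, ymin = .data$h_low,
                                        ymax = .data$h_high,
                                        group = .data$vessel),
                           width = 0, colour = "firebrick", alpha = 0.5) +
    ggplot2::geom_point(data = tr,
                        ggplot2::aes(x = .data$t, y = .data$h,
                                     group = .data$vessel),
                        colour = "firebrick", size = 1) +
    ggplot2::labs(x = "time (s)", y = "waterfront height (µm)") +
    ggplot2::theme_minimal()
}

#' Plot an alignment objective curve
#'
#' @param object An `alignment_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.alignment_result <- function(object, ...) {
  df <- object$objective_curve
  ggplot2::ggplot(df, ggplot2::aes(x = .data$candidate, y = .data$objective)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$estimate, linetype = 2,
                        colour = "firebrick") +
    ggplot2::labs(x = object$what, y = "normalised l² objective") +
    ggplot2::theme_minimal()
}

#' Plot PDHG convergence of a reconstruction
#'
#' @param volume A [pdhg_reconstruct()] result (carries a `convergence`
#'   attribute).
#' @return A ggplot object.
#' @export
plot_convergence <- function(volume) {
  cv <- attr(volume, "convergence")
  if (is.null(cv)) stop("no convergence log attached")
  ggplot2::ggplot(cv, ggplot2::aes(x = .data$iteration, y = .data$objective)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "PDHG iteration", y = "objective (solver scale)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot .data
#' @export
ggplot2::autoplot
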