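#' Plot an incubation result
#'
#' `type = "polydispersity"` shows the coarsening readout s/d against time;
#' `type = "radii"` shows every droplet's radius trajectory.
#'
#' @param object An `incubation_result`.
#' @param type One of `"polydispersity"`, `"radii"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot incubation_result
#' @export
autoplot.incubation_result <- function(object,
                                       type = c("polydispersity", "radii"),
                                       ...) {
  type <- match.arg(type)
  if (type == "polydispersity") {
    ggplot2::ggplot(object$summary,
                    ggplot2::aes(x = .data$time_s, y = .data$s_over_d)) +
      ggplot2::geom_line() +
      ggplot2::geom_point(size = 0.8) +
      ggplot2::labs(x = "time (s)", y = "polydispersity s/d",
                    title = "Osmosis-driven coarsening") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(object$trajectory,
                    ggplot2::aes(x = .data$time_s, y = .data$radius_um,
                                 group = .data$droplet_id)) +
      ggplot2::geom_line(alpha = 0.4) +
      ggplot2::labs(x = "time (s)", y = "radius (um)",
                    title = "Per-droplet radius trajectories") +
      ggplot2::theme_minimal()
  }
}

#' Plot an evolution run
#'
#' Shows the mean end-of-incubation diameter (the selected trait), the
#' per-generation Price terms, and s/d across generations.
#'
#' @param object An `evolution_run`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot evolution_run
#' @export
autoplot.evolution_run <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$summary[, c("generation", "z_bar_um", "cov_term",
                       "transmission_term", "s_over_d")],
    -"generation", names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$generation, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "generation", y = NULL,
                  title = "Recursive droplet evolution") +
    ggplot2::theme_minimal()
}

#' Plot a synthetic micrograph with its ground truth
#'
#' @param object A `synthetic_frame`.
#' @param show_truth Overlay ground-truth circles?
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot synthetic_frame
#' @export
autoplot.synthetic_frame <- function(object, show_truth = TRUE, ...) {
  px <- object$pixels
  df <- expand.grid(x = seq_len(nrow(px)), y = seq_len(ncol(px)))
  df$intensity <- as.vector(px)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 255)) +
    ggplot2::coord_fixed() +
    ggplot2::theme_void() +
    ggplot2::labs(title = sprintf("t = %g s", object$time_s))
  if (show_truth && nrow(object$ground_truth) > 0) {
    p <- p + ggplot2::geom_point(
      data = object$ground_truth,
      ggplot2::aes(x = .data$x_px, y = .data$y_px),
      colour = "red", shape = 3, size = 1
    )
  }
  p
}
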