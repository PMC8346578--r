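#' Plot species' range distributions at selected times
#'
#' Density against latitude (patch index), one curve per species coloured
#' by its initial temperature adaptation, faceted by snapshot time --- the
#' standard way to visualise poleward range shifts in this model.
#'
#' @param object An `ee_trajectory`.
#' @param times Snapshot times to facet (defaults to onset of warming, end
#'   of warming, end of simulation).
#' @param level Trophic level(s) to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ee_trajectory <- function(object,
                                   times = c(0, object$config$times$t_E,
                                             object$config$times$t_end),
                                   level = "resource", ...) {
  dat <- object$states |>
    dplyr::filter(.data$time %in% times, .data$level %in% {{ level }})
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$patch, y = .data$density,
                                    colour = factor(.data$species),
                                    group = .data$species)) +
    ggplot2::geom_line(show.legend = FALSE) +
    ggplot2::scale_colour_viridis_d(option = "plasma") +
    ggplot2::facet_wrap(~time, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "patch (1 = pole)", y = "density") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot mean local richness over time
#'
#' Points show the landscape mean of local (per-patch) species richness at
#' each snapshot; the ribbon spans one standard deviation across patches.
#'
#' @param trajectory An `ee_trajectory`.
#' @param from Earliest time shown (default: onset of climate change).
#' @inheritParams local_richness
#' @return A ggplot object.
#' @export
plot_richness <- function(trajectory, from = 0,
                          threshold = trajectory$config$defaults$presence_threshold,
                          level = "resource") {
  dat <- richness_summary(trajectory, threshold, level) |>
    dplyr::filter(.data$time >= from)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$time, y = .data$mean_richness)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_richness - .data$sd_richness,
                                      ymax = .data$mean_richness + .data$sd_richness),
                         alpha = 0.25) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = trajectory$config$times$t_E,
                        linetype = "dotted") +
    ggplot2::labs(x = "time (yr)", y = "species per patch") +
    ggplot2::theme_minimal()
}

#' Plot integrated trait lag against trait dispersion across realisations
#'
#' @param data A data frame with columns `lag`, `dispersion`, and
#'   optionally grouping columns (e.g. `dispersal`, `variance`) mapped to
#'   colour via `colour_by`.
#' @param colour_by Optional name of a column to colour points by.
#' @return A ggplot object with an OLS line per panel.
#' @export
plot_lag_dispersion <- function(data, colour_by = NULL) {
  p <- ggplot2::ggplot(data, ggplot2::aes(x = .data$dispersion, y = .data$lag))
  if (!is.null(colour_by)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data[[colour_by]]))
  } else {
    p <- p + ggplot2::geom_point()
  }
  p +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "grey30", linewidth = 0.5) +
    ggplot2::labs(x = "trait dispersion (degC^2)", y = "trait lag (degC)") +
    ggplot2::theme_minimal()
}
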