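# ggplot2 views of the result types.

#' Plot a stand-density profile
#'
#' @param profile a [density_profile()] tibble (optionally with `year` /
#'   `repeat` columns, which become facets/colours).
#' @param log10 show density on a log axis (zeros dropped).
#' @return A ggplot object.
#' @export
plot_density_profile <- function(profile, log10 = FALSE) {
  p <- ggplot2::ggplot(profile,
                       ggplot2::aes(x = .data$bin_start_km,
                                    y = .data$stems_per_ha)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "distance along transect (km)",
                  y = "stems per ha (trees > 1.3 m)")
  if ("year" %in% names(profile)) {
    p <- p + ggplot2::aes(colour = factor(.data$year)) +
      ggplot2::labs(colour = "year")
  }
  if (log10) p <- p + ggplot2::scale_y_log10()
  p
}

#' @rdname lag_trajectory
#' @param object a `lag_trajectory`.
#' @param ... unused.
#' @method autoplot lag_trajectory
#' @export
autoplot.lag_trajectory <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$analogue_fraction,
                               y = .data$simulated_fraction)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_path(arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm"),
                                              type = "closed")) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      x = "climate-analogue position (fraction of corridor)",
      y = "simulated treeline position (fraction of corridor)",
      caption = "below diagonal: migration lag; above: overshoot")
}

#' @rdname tundra_series
#' @param object a `tundra_series`.
#' @param ... unused.
#' @method autoplot tundra_series
#' @export
autoplot.tundra_series <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$year,
                               y = .data$fraction_of_initial,
                               colour = .data$region)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "year CE", y = "remaining tundra (fraction of initial)")
}

#' @rdname run_simulation
#' @param object a `treeline_sim`.
#' @method autoplot treeline_sim
#' @export
autoplot.treeline_sim <- function(object, ...) {
  log <- filter(object$log, .data$phase == "main")
  ggplot2::ggplot(log,
                  ggplot2::aes(x = .data$year,
                               y = .data$northernmost_stem_m / 1000,
                               group = .data$repeat_id,
                               colour = factor(.data$repeat_id))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "year CE", y = "northernmost stem (km)",
                  colour = "repeat")
}

#' @rdname run_experiment
#' @param object a `treeline_experiment`.
#' @method autoplot treeline_experiment
#' @export
autoplot.treeline_experiment <- function(object, ...) {
  tun <- filter(object$tundra, .data$region == "total")
  ggplot2::ggplot(tun,
                  ggplot2::aes(x = .data$year,
                               y = .data$fraction_of_initial,
                               colour = .data$scenario,
                               linetype = .data$post_peak)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$region_name)) +
    ggplot2::labs(x = "year CE", y = "remaining tundra (fraction of initial)")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
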