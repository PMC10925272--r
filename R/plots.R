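#' Plot a signal trace
#'
#' Effective signal, inhibitor and the positive part against time, with the
#' stimulation window shaded.
#'
#' @param object A `signal_trace` from [integrate_signal()].
#' @param protocol Optional [stimulus_protocol()] used to shade the
#'   stimulation window.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.signal_trace <- function(object, protocol = NULL, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[c("time_h", "s_eff", "inhibitor", "s_eff_plus")],
    -"time_h",
    names_to = "species", values_to = "value"
  )
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$time_h, .data$value,
    colour = .data$species
  )) +
    shade_stimulation(protocol) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "time (h)", y = "signal (dimensionless)", colour = NULL
    ) +
    ggplot2::theme_minimal()
  p
}

#' Plot region velocity traces
#'
#' @param object A `region_traces` tibble.
#' @param protocol Optional protocol for shading the stimulation window.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.region_traces <- function(object, protocol = NULL, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object), -"time_h",
    names_to = "region", values_to = "v", names_prefix = "v_"
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$time_h, .data$v,
    colour = .data$region
  )) +
    shade_stimulation(protocol) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (h)", y = "x-velocity (um/h)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a 1D density kymograph
#'
#' @param object A `kymograph_1d` from [solve_rad_1d()].
#' @param ... Unused.
#' @return A ggplot raster of density over space and time.
#' @export
autoplot.kymograph_1d <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object), ggplot2::aes(
    .data$x, .data$time_h,
    fill = .data$rho
  )) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "density\n(cells/mm)") +
    ggplot2::labs(x = "x (mm)", y = "time (h)") +
    ggplot2::theme_minimal()
}

#' Plot a 2D density field
#'
#' @param object A `density_field_2d`.
#' @param ... Unused.
#' @return A ggplot raster.
#' @export
autoplot.density_field_2d <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object), ggplot2::aes(
    .data$x, .data$y,
    fill = .data$rho
  )) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "density") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)") +
    ggplot2::theme_minimal()
}

#' Plot marginal posteriors of a fit
#'
#' @param object An `electro_fit`.
#' @param type `"density"` for marginal posterior densities, `"trace"` for
#'   per-chain trace plots.
#' @param ... Unused.
#' @return A ggplot object faceted by parameter.
#' @export
autoplot.electro_fit <- function(object, type = c("density", "trace"), ...) {
  type <- match.arg(type)
  draws <- object$posterior$draws
  draws$.iter <- stats::ave(
    seq_len(nrow(draws)), draws$.chain,
    FUN = seq_along
  )
  long <- tidyr::pivot_longer(draws, -c(".chain", ".iter"),
    names_to = "parameter", values_to = "value"
  )
  if (type == "density") {
    ggplot2::ggplot(long, ggplot2::aes(.data$value)) +
      ggplot2::geom_density(fill = "steelblue", alpha = 0.4) +
      ggplot2::facet_wrap(~parameter, scales = "free") +
      ggplot2::labs(x = NULL, y = "posterior density") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(long, ggplot2::aes(.data$.iter, .data$value,
      colour = factor(.data$.chain)
    )) +
      ggplot2::geom_line(alpha = 0.6) +
      ggplot2::facet_wrap(~parameter, scales = "free_y") +
      ggplot2::labs(x = "iteration (post burn-in)", y = NULL,
        colour = "chain"
      ) +
      ggplot2::theme_minimal()
  }
}

#' Plot a size sweep
#'
#' Maximum electrotaxis velocity against tissue size.
#'
#' @param sweep Output of [size_sweep()] (optionally several, row-bound
#'   with a `shape` column).
#' @return A ggplot object.
#' @export
plot_size_sweep <- function(sweep) {
  aes <- if ("shape" %in% names(sweep)) {
    ggplot2::aes(.data$size_mm, .data$v_max_um_h, colour = .data$shape)
  } else {
    ggplot2::aes(.data$size_mm, .data$v_max_um_h)
  }
  ggplot2::ggplot(sweep, aes) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "tissue size (mm)",
      y = "max electrotaxis velocity (um/h)"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a designed field map
#'
#' Field direction (arrows, subsampled) over the field magnitude.
#'
#' @param object A `field_map`.
#' @param every Arrow subsampling stride in grid cells.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.field_map <- function(object, every = 6, ...) {
  d <- tibble::as_tibble(object)
  xv <- sort(unique(d$x))
  yv <- sort(unique(d$y))
  sub <- dplyr::filter(
    d,
    .data$x %in% xv[seq(1, length(xv), every)],
    .data$y %in% yv[seq(1, length(yv), every)],
    .data$mask
  )
  sc <- attr(object, "spacing") * every * 0.8 /
    max(sub$magnitude, .Machine$double.eps)
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$magnitude)) +
    ggplot2::geom_segment(
      data = sub,
      ggplot2::aes(
        xend = .data$x + sc * .data$ex,
        yend = .data$y + sc * .data$ey
      ),
      arrow = ggplot2::arrow(length = ggplot2::unit(1.2, "mm")),
      colour = "white", linewidth = 0.25
    ) +
    ggplot2::scale_fill_viridis_c(name = "|field|") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)") +
    ggplot2::theme_minimal()
}

shade_stimulation <- function(protocol) {
  if (is.null(protocol)) {
    return(NULL)
  }
  win <- stimulation_window(protocol)
  if (anyNA(win)) {
    return(NULL)
  }
  ggplot2::annotate("rect",
    xmin = win["on"], xmax = win["off"],
    ymin = -Inf, ymax = Inf, alpha = 0.12, fill = "red"
  )
}
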