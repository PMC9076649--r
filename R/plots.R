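#' Plot a particle pattern
#'
#' Draws the pill face and its particles in their display colors, in the
#' y-down image frame (the y axis is reversed so the plot matches a
#' photograph).
#'
#' @param particles particle tibble (`x`, `y`, `color`).
#' @param palette a [candy_palette()]; defaults to the pattern's alphabet.
#' @param show_graph overlay the Delaunay neighbor graph.
#' @return A ggplot object.
#' @export
plot_candycode <- function(particles, palette = NULL, show_graph = FALSE) {
  particles <- validate_particles(particles)
  palette <- palette %||% candy_palette(attr(particles, "alphabet") %||%
                                          candy_alphabet("A"))
  cols <- setNames(
    grDevices::rgb(palette$r, palette$g, palette$b),
    palette$name
  )
  p <- ggplot2::ggplot(particles, ggplot2::aes(x = .data$x, y = .data$y))
  if (show_graph) {
    g <- delaunay_graph(particles)
    seg <- tibble(
      x = particles$x[g$edges$from], y = particles$y[g$edges$from],
      xend = particles$x[g$edges$to], yend = particles$y[g$edges$to]
    )
    p <- p + ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend),
      linewidth = 0.2, color = "grey60"
    )
  }
  p +
    ggplot2::geom_point(ggplot2::aes(fill = .data$color), shape = 21,
                        size = 3, color = "grey20") +
    ggplot2::scale_fill_manual(values = cols, guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}

#' Plot a library-size sweep and its scaling fit
#'
#' Mean maximum shared strings (with +-1 sd error bars) against library size
#' on a log axis, with the fitted log-linear trend when a fit is supplied.
#'
#' @param sweep a [run_sweep()] tibble.
#' @param fit optional [fit_scaling()] object.
#' @return A ggplot object.
#' @export
plot_sweep <- function(sweep, fit = NULL) {
  s <- summarise_sweep(sweep)
  p <- ggplot2::ggplot(s, ggplot2::aes(x = .data$size,
                                       y = .data$mean_max_shared)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_max_shared - .data$sd_max_shared,
                   ymax = .data$mean_max_shared + .data$sd_max_shared),
      width = 0.05
    ) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "library size",
                  y = "max shared strings (mean over replicates)")
  if (!is.null(fit)) {
    p <- p + ggplot2::geom_function(
      fun = function(x) fit$intercept + fit$slope_per_decade * log10(x),
      color = "red"
    )
  }
  p
}

#' @describeIn fit_scaling plot the per-size means and the fitted line.
#' @param object a `scaling_fit`.
#' @export
autoplot.scaling_fit <- function(object, ...) {
  s <- object$summary
  ggplot2::ggplot(s, ggplot2::aes(x = .data$size,
                                  y = .data$mean_max_shared)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_max_shared - .data$sd_max_shared,
                   ymax = .data$mean_max_shared + .data$sd_max_shared),
      width = 0.05
    ) +
    ggplot2::geom_point() +
    ggplot2::geom_function(
      fun = function(x) object$intercept +
        object$slope_per_decade * log10(x),
      color = "red"
    ) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "library size",
                  y = "max shared strings (mean over replicates)")
}

#' @describeIn db_query plot the shared-count histogram of a match report.
#' @param object a `candy_match`.
#' @export
autoplot.candy_match <- function(object, ...) {
  ggplot2::ggplot(object$histogram,
                  ggplot2::aes(x = .data$shared, y = .data$codes)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "shared strings with suspect",
                  y = "database codes",
                  title = sprintf("%s: %s", object$suspect_id,
                                  object$verdict))
}
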