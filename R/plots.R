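#' Plot a single-molecule trace with its idealized path
#'
#' @param frames frames tibble (e.g. `idealize_traces()$frames` or the
#'   traces of one molecule).
#' @param molecule molecule id to plot; default the first present.
#' @return a ggplot object: intensity over time with, when a `level`
#'   column is present, the idealized path overlaid in red.
#' @export
plot_trace <- function(frames, molecule = NULL) {
  if (is.null(molecule)) molecule <- frames$molecule_id[1]
  g <- frames[frames$molecule_id == molecule, ]
  p <- ggplot2::ggplot(g, ggplot2::aes(x = .data$time_s,
                                       y = .data$intensity)) +
    ggplot2::geom_line(color = "grey40", linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "normalized intensity",
                  title = molecule) +
    ggplot2::theme_minimal()
  if ("level" %in% names(g)) {
    p <- p + ggplot2::geom_step(ggplot2::aes(y = .data$level),
                                color = "red", linewidth = 0.6)
  }
  p
}

#' Heatmap of a transition density plot
#'
#' Mirrors the usual TDP presentation: initial intensity on x, final on y,
#' density as a gradient, with the number of analyzed transitions
#' annotated.
#'
#' @param object a [build_tdp()] result.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.tk_tdp <- function(object, ...) {
  df <- tidy.tk_tdp(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$initial, y = .data$final,
                                   fill = .data$density)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "initial normalized intensity",
                  y = "final normalized intensity",
                  subtitle = sprintf("n = %d transitions",
                                     object$n_transitions)) +
    ggplot2::theme_minimal()
}

#' Population histogram with its multipeak Gaussian fit
#'
#' Bars with standard errors, dashed per-peak Gaussians and the solid
#' composite model.
#'
#' @param object a [fit_multipeak()] result.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.tk_histfit <- function(object, ...) {
  h <- object$histogram
  df <- tibble::tibble(x = h$bin_mid, count = h$count, se = h$se,
                       model = object$fitted)
  xs <- seq(min(h$bin_mid), max(h$bin_mid), length.out = 300)
  comp <- purrr::pmap(object$peaks, function(state, amplitude, center,
                                             width, ...) {
    tibble::tibble(state = factor(state), x = xs,
                   y = object$y0 +
                     amplitude * exp(-((xs - center) / width)^2))
  })
  comp <- dplyr::bind_rows(comp)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$count)) +
    ggplot2::geom_col(fill = "grey80", width = diff(h$bin_mid[1:2]) * 0.9) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$count - .data$se,
                                        ymax = .data$count + .data$se),
                           width = 0, color = "grey50") +
    ggplot2::geom_line(data = comp,
                       ggplot2::aes(y = .data$y, group = .data$state),
                       linetype = "dashed", color = "steelblue") +
    ggplot2::geom_line(ggplot2::aes(y = .data$model), color = "black") +
    ggplot2::labs(x = "normalized intensity", y = "frames") +
    ggplot2::theme_minimal()
}

#' Dwell-time histogram with exponential fits
#'
#' @param object a [fit_exponentials()] result.
#' @param ... unused.
#' @return a ggplot object showing the binned dwell counts with the mono
#'   (and, when fitted, bi) exponential curves.
#' @export
autoplot.tk_expfit <- function(object, ...) {
  b <- object$bins
  xs <- seq(min(b$mid), max(b$mid), length.out = 200)
  curves <- list(tibble::tibble(
    model = "mono", x = xs, y = object$mono$A * exp(-object$mono$k * xs)))
  if (!is.null(object$bi)) {
    curves[[2]] <- tibble::tibble(
      model = "bi", x = xs,
      y = object$bi$A1 * exp(-object$bi$k1 * xs) +
        object$bi$A2 * exp(-object$bi$k2 * xs))
  }
  curves <- dplyr::bind_rows(curves)
  ggplot2::ggplot(b, ggplot2::aes(x = .data$mid, y = .data$count)) +
    ggplot2::geom_col(fill = "grey80", width = diff(b$mid[1:2]) * 0.9) +
    ggplot2::geom_line(data = curves,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    color = .data$model)) +
    ggplot2::labs(x = "dwell time (s)", y = "transitions",
                  color = "fit") +
    ggplot2::theme_minimal()
}
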