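#' Plot methods
#'
#' `autoplot()` methods for the main result types: division-rate series,
#' growth decompositions, arrest-probability fits, deformation fields and
#' simulated class counts.
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @name histogrowth-autoplot
NULL

#' @rdname histogrowth-autoplot
#' @export
autoplot.rate_series <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$rate)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (hAPF)", y = "division rate (1/h per cell)",
                  title = paste0("top-hat window ", attr(object, "window"),
                                 " h")) +
    ggplot2::theme_minimal()
}

#' @rdname histogrowth-autoplot
#' @export
autoplot.growth_decomposition <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object),
    dplyr::starts_with("cum_"),
    names_to = "component", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value,
                                     color = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (hAPF)", y = "cumulative log area expansion") +
    ggplot2::theme_minimal()
}

#' @rdname histogrowth-autoplot
#' @export
autoplot.arrest_fit <- function(object, ...) {
  emp <- object$empirical
  gg <- ggplot2::ggplot(emp, ggplot2::aes(x = .data$bin_mid)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$p_hat, size = .data$n_div),
                        alpha = 0.6) +
    ggplot2::labs(x = "division time (hAPF)",
                  y = "P(>= 1 arrested daughter)", size = "divisions") +
    ggplot2::theme_minimal()
  if (!is.null(object$p_fit) && object$p_fit$converged) {
    grid <- tibble::tibble(t = seq(min(emp$bin_mid), max(emp$bin_mid),
                                   length.out = 200))
    cf <- object$p_fit$coef
    grid$p <- hill(grid$t, cf[["t_half"]], cf[["exponent"]],
                   cf[["plateau"]])
    gg <- gg + ggplot2::geom_line(data = grid,
                                  ggplot2::aes(x = .data$t, y = .data$p),
                                  color = "firebrick")
  }
  gg
}

#' @rdname histogrowth-autoplot
#' @export
autoplot.deformation_field <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$y,
                                       color = .data$area_change)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::coord_equal() +
    ggplot2::scale_color_gradient2() +
    ggplot2::labs(x = "x / R (AP)", y = "y / R (DV)",
                  color = "rel. area change") +
    ggplot2::theme_minimal()
}

#' @rdname histogrowth-autoplot
#' @export
autoplot.sim_result <- function(object, ...) {
  counts <- class_counts(object)
  long <- tidyr::pivot_longer(counts, c("cycling", "arrested", "sop",
                                        "total"),
                              names_to = "class", values_to = "count")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$count,
                                     color = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (hAPF)", y = "cells") +
    ggplot2::theme_minimal()
}
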