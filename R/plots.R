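#' Plot a DPPH kinetic trace
#'
#' @param object A [dpph_trace()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot dpph_trace
#' @export
autoplot.dpph_trace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time_min, .data$abs515)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "time (min)", y = "A515 (AU)",
                  title = paste0("DPPH decay, ratio = ",
                                 signif(object$ratio[1], 3))) +
    ggplot2::theme_minimal()
}

#' Plot a dose-response table with its fitted Hill curve
#'
#' @param object An `ec50_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ec50_fit
#' @export
autoplot.ec50_fit <- function(object, ...) {
  d <- object$data
  grid <- tibble::tibble(ratio = seq(min(d$ratio), max(d$ratio),
                                     length.out = 200))
  grid$fit <- 100 * grid$ratio^object$hill_n /
    (object$ec50^object$hill_n + grid$ratio^object$hill_n)
  ggplot2::ggplot(d, ggplot2::aes(.data$ratio, .data$percent_reduced)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$fit),
                       colour = "firebrick") +
    ggplot2::geom_hline(yintercept = 50, linetype = 3) +
    ggplot2::geom_vline(xintercept = object$ec50, linetype = 3) +
    ggplot2::labs(x = "antioxidant / DPPH (uM/uM)", y = "% DPPH reduced",
                  title = sprintf("EC50 = %.3g uM/uM (Hill n = %.2f)",
                                  object$ec50, object$hill_n)) +
    ggplot2::theme_minimal()
}

#' Plot a product-accumulation time course
#'
#' @param object A [timecourse()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot timecourse
#' @export
autoplot.timecourse <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time_min, .data$conc_uM,
                                       colour = .data$product)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "time (min)", y = "product (uM)") +
    ggplot2::theme_minimal()
}

#' Plot geometric scores against the classification regions
#'
#' Displays each intermediate in the (torsion deviation, carbon
#' displacement) plane with the productive window shaded.
#'
#' @param object A `product_prediction` from [predict_products()] (or any
#'   tibble with `d_cn_c4`, `delta_theta` and an id column).
#' @param thresholds A [geo_thresholds()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot product_prediction
#' @export
autoplot.product_prediction <- function(object,
                                        thresholds = geo_thresholds(), ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$delta_theta, .data$d_cn_c4)) +
    ggplot2::annotate("rect", xmin = thresholds$dtheta_lo,
                      xmax = thresholds$dtheta_hi, ymin = 0,
                      ymax = thresholds$d_max, alpha = 0.15,
                      fill = "forestgreen") +
    ggplot2::geom_hline(yintercept = thresholds$d_max, linetype = 3) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$label), size = 3) +
    ggplot2::geom_text(ggplot2::aes(label = .data$id),
                       vjust = -1, size = 3) +
    ggplot2::labs(x = "delta theta (deg)", y = "d(Cn-C4) (A)",
                  shape = "class") +
    ggplot2::theme_minimal()
}
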