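#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a layer profile
#'
#' Relative marker intensity against layer index with the selection cutoff
#' drawn as a horizontal reference.
#'
#' @param object A `layer_profile`.
#' @param cutoff Reference cutoff line (default 0.01).
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.layer_profile <- function(object, cutoff = 0.01, ...) {
  ggplot2::ggplot(object[object$defined, ],
                  ggplot2::aes(x = .data$layer, y = .data$r)) +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::geom_hline(yintercept = cutoff, linetype = 2, colour = "red") +
    ggplot2::labs(x = "layer (z index)", y = "relative marker intensity") +
    ggplot2::theme_minimal()
}

#' Plot a cutoff scan
#'
#' Youden's index across candidate cutoffs with the selected cutoff marked.
#'
#' @param object A `cutoff_scan`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.cutoff_scan <- function(object, ...) {
  ggplot2::ggplot(object$scan,
                  ggplot2::aes(x = .data$cutoff, y = .data$j)) +
    ggplot2::geom_step() +
    ggplot2::geom_vline(xintercept = object$selected$cutoff,
                        linetype = 2, colour = "red") +
    ggplot2::labs(x = "expression cutoff", y = "Youden's J") +
    ggplot2::theme_minimal()
}

#' Plot Kaplan-Meier curves
#'
#' @param object A `km_compare`.
#' @param ... Unused.
#' @return A ggplot of the two product-limit curves.
#' @exportS3Method ggplot2::autoplot
autoplot.km_compare <- function(object, ...) {
  ggplot2::ggplot(object$curves,
                  ggplot2::aes(x = .data$time, y = .data$surv,
                               colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time", y = "survival probability",
                  subtitle = sprintf("log-rank p = %.3g", object$p)) +
    ggplot2::theme_minimal()
}
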