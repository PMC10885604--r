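#' Plot a meta-gene stop-codon profile
#'
#' Mean reactivity against position relative to the stop codon, with the
#' stop codon shaded.
#'
#' @param object A `metagene_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot metagene_profile
#' @export
autoplot.metagene_profile <- function(object, ...) {
  ggplot2::ggplot(object$profile,
                  ggplot2::aes(x = .data$rel_pos, y = .data$mean_reactivity)) +
    ggplot2::annotate("rect", xmin = -0.5, xmax = 2.5, ymin = -Inf, ymax = Inf,
                      alpha = 0.15) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Position relative to stop codon (nt)",
                  y = "Mean DMS reactivity") +
    ggplot2::theme_minimal()
}

#' Plot cumulative curves for a group comparison
#'
#' @param object A `utr_group_compare`.
#' @param ... Unused.
#' @return A ggplot object (ECDF per group, p-value in the subtitle).
#' @method autoplot utr_group_compare
#' @export
autoplot.utr_group_compare <- function(object, ...) {
  ggplot2::ggplot(object$ecdf,
                  ggplot2::aes(x = .data$value, y = .data$ecdf,
                               colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = object$value_field, y = "Cumulative fraction",
                  subtitle = sprintf("%s p = %.3g", object$test,
                                     object$p_value)) +
    ggplot2::theme_minimal()
}

#' Plot a gene-level correlation scatter
#'
#' @param object A `utr_correlation`.
#' @param ... Unused.
#' @return A ggplot object with the fitted line and R in the subtitle.
#' @method autoplot utr_correlation
#' @export
autoplot.utr_correlation <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::labs(x = object$x_field,
                  y = if (object$log_y) paste0("log10(", object$y_field, ")")
                      else object$y_field,
                  subtitle = sprintf("Pearson R = %.3f, p = %.3g",
                                     object$r, object$p_value)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
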