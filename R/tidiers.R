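#' Tidy a group comparison
#'
#' @param x A `utr_group_compare` object.
#' @param ... Unused.
#' @return The per-group summary tibble.
#' @method tidy utr_group_compare
#' @export
tidy.utr_group_compare <- function(x, ...) x$summary

#' @rdname tidy.utr_group_compare
#' @return For `glance()`: a one-row tibble with the test, statistic and
#'   p-value.
#' @method glance utr_group_compare
#' @export
glance.utr_group_compare <- function(x, ...) {
  tibble(test = x$test, statistic = x$statistic, p_value = x$p_value,
         group_field = x$group_field, value_field = x$value_field)
}

#' Tidy a correlation result
#'
#' @param x A `utr_correlation` object.
#' @param ... Unused.
#' @return The scatter tibble (`x`, `y` as analyzed).
#' @method tidy utr_correlation
#' @export
tidy.utr_correlation <- function(x, ...) x$data

#' @rdname tidy.utr_correlation
#' @method glance utr_correlation
#' @export
glance.utr_correlation <- function(x, ...) {
  tibble(r = x$r, p_value = x$p_value, n = x$n,
         x_field = x$x_field, y_field = x$y_field, log_y = x$log_y)
}

#' Tidy a decay fit
#'
#' @param x A `decay_fit` object.
#' @param ... Unused.
#' @return The normalized time course with fitted values.
#' @method tidy decay_fit
#' @export
tidy.decay_fit <- function(x, ...) {
  mutate(x$data, fitted = exp(x$intercept - x$k * .data$time))
}

#' @rdname tidy.decay_fit
#' @method glance decay_fit
#' @export
glance.decay_fit <- function(x, ...) {
  tibble(k = x$k, t_half = x$t_half, r_squared = x$r_squared, n = x$n)
}

#' Tidy a meta-gene profile
#'
#' @param x A `metagene_profile` object.
#' @param ... Unused.
#' @return The per-position profile tibble.
#' @method tidy metagene_profile
#' @export
tidy.metagene_profile <- function(x, ...) x$profile

#' @rdname tidy.metagene_profile
#' @method glance metagene_profile
#' @export
glance.metagene_profile <- function(x, ...) {
  tibble(cds_mean = x$cds_vs_utr$cds_mean, utr_mean = x$cds_vs_utr$utr_mean,
         statistic = x$cds_vs_utr$statistic, p_value = x$cds_vs_utr$p_value,
         n_used = x$n_used, n_skipped = x$n_skipped)
}
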