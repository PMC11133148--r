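#' Violin display of fit-index distributions by scenario grouping
#'
#' @param result A `gof_simulation`.
#' @param response Index column to display.
#' @param by Record column defining the x-axis groups.
#' @return A ggplot object.
#' @export
plot_gof_distributions <- function(result, response = "cfi",
                                   by = "estimator") {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plotting requires the 'ggplot2' package", call. = FALSE)
  records <- if (inherits(result, "gof_simulation")) result$records else result
  records <- records[records$converged & !is.na(records[[response]]), ]
  df <- data.frame(g = factor(records[[by]]), y = records[[response]])
  ggplot2::ggplot(df, ggplot2::aes(x = g, y = y)) +
    ggplot2::geom_violin(scale = "width") +
    ggplot2::stat_summary(fun = stats::median, geom = "point") +
    ggplot2::labs(x = by, y = response)
}

#' Conditional-median trace of a fit index
#'
#' @inheritParams plot_gof_distributions
#' @param x_var Record column on the x-axis.
#' @param group_var Record column mapped to line colour.
#' @export
plot_median_profiles <- function(result, response = "cfi",
                                 x_var = "estimator",
                                 group_var = "misspec_magnitude") {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plotting requires the 'ggplot2' package", call. = FALSE)
  med <- median_profiles(result, condition_on = c(x_var, group_var),
                         response = response)
  df <- data.frame(x = factor(med[[x_var]]), y = med$median,
                   g = factor(med[[group_var]]))
  ggplot2::ggplot(df, ggplot2::aes(x = x, y = y, colour = g, group = g)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = x_var, y = paste("median", response),
                  colour = group_var)
}
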