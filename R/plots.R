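#' Plot a fitted yield-potential frontier
#'
#' Bin upper-decile means and the fitted zero-intercept line; when `plots`
#' is supplied the raw yield-LI cloud is drawn underneath.
#'
#' @param object An `li_frontier` fit.
#' @param plots Optional plot table for the background cloud.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot li_frontier
autoplot.li_frontier <- function(object, plots = NULL, ...) {
  binmeans <- tidy(object) |> filter(.data$usable)
  p <- ggplot2::ggplot()
  if (!is.null(plots)) {
    p <- p + ggplot2::geom_point(
      data = plots,
      ggplot2::aes(x = .data$light_interception * 100,
                   y = .data$yield_kernel_lbs_acre),
      alpha = 0.15, size = 0.4, colour = "grey40")
  }
  p +
    ggplot2::geom_abline(slope = object$slope, intercept = 0,
                         colour = "red", linetype = "dashed") +
    ggplot2::geom_point(
      data = binmeans,
      ggplot2::aes(x = .data$li_decile_mean_pct, y = .data$yield_decile_mean),
      colour = "red", size = 2) +
    ggplot2::labs(
      x = "Light interception (%)", y = "Kernel yield (lbs/acre)",
      title = sprintf("Yield-potential frontier: %.1f lbs/acre per %%LI (R² = %.2f)",
                      object$slope, object$r2_binmeans))
}

#' Plot a variable-importance table
#'
#' @param object An `importance_table` from [importance_incmse()].
#' @param top_n Number of features shown (default 15).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot importance_table
autoplot.importance_table <- function(object, top_n = 15, ...) {
  d <- head(object, top_n)
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$inc_mse_pct,
    y = stats::reorder(.data$feature, .data$inc_mse_pct))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "%IncMSE (out-of-bag)", y = NULL,
                  title = "Permutation variable importance")
}

#' Plot a partial-dependence curve
#'
#' @param object A `pdp_curve` from [partial_dependence()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot pdp_curve
autoplot.pdp_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$value, y = .data$response)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = attr(object, "feature"), y = "Partial response",
                  title = sprintf("Partial dependence: %s",
                                  attr(object, "feature")))
}

#' Plot per-fold cross-validation metrics
#'
#' @param object A `cv_report` from [cross_validate()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot cv_report
autoplot.cv_report <- function(object, ...) {
  d <- as_tibble(object) |>
    tidyr::pivot_longer(c("rmse", "r2", "rpiq"), names_to = "metric")
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$fold), y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "Fold", y = NULL,
                  title = sprintf("%d-fold cross-validation", attr(object, "k")))
}
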