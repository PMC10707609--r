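# ggplot2 figures for agreement analyses: per-method box plots, regression
# scatter plots and Bland-Altman plots.

#' Box plot of per-method MRD1 distributions
#'
#' @param data Cohort data frame.
#' @param cols Measurement columns (mm).
#' @return A ggplot object.
#' @export
plot_method_box <- function(data, cols = intersect(DEFAULT_METHODS, names(data))) {
  long <- tidyr::pivot_longer(dplyr::select(as_tibble(data), dplyr::all_of(cols)),
                              dplyr::everything(),
                              names_to = "method", values_to = "mrd1_mm")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$method, y = .data$mrd1_mm,
                                     fill = .data$method)) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "MRD1 (mm)") +
    ggplot2::theme_minimal()
}

#' Scatter plot with fitted regression line for a method pair
#'
#' @param data Cohort data frame.
#' @param x,y Column names (predictor, response).
#' @return A ggplot object annotated with slope and R-squared.
#' @export
plot_regression <- function(data, x, y) {
  fit <- linear_fit(data[[x]], data[[y]])
  ggplot2::ggplot(data, ggplot2::aes(x = .data[[x]], y = .data[[y]])) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(slope = fit$slope, intercept = fit$intercept,
                         colour = "steelblue") +
    ggplot2::labs(title = sprintf("slope = %.2f, R² = %.3f",
                                  fit$slope, fit$r.squared),
                  x = paste(x, "(mm)"), y = paste(y, "(mm)")) +
    ggplot2::theme_minimal()
}

#' Bland-Altman plot for a method pair
#'
#' Plots per-eye differences (`x - y`) against pair means with the mean
#' difference and limits of agreement as horizontal lines.
#'
#' @param data Cohort data frame.
#' @param x,y Column names.
#' @param multiplier LOA multiplier.
#' @return A ggplot object.
#' @export
plot_bland_altman <- function(data, x, y, multiplier = 1.96) {
  ba <- bland_altman(data[[x]], data[[y]], multiplier)
  df <- tibble(avg = (data[[x]] + data[[y]]) / 2,
               diff = data[[x]] - data[[y]])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$avg, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = ba$mean_diff, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = c(ba$loa_lo, ba$loa_hi),
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(title = sprintf("%s - %s: mean diff %.3f, ΔLOA %.3f",
                                  x, y, ba$mean_diff, ba$delta_loa),
                  x = "pair mean (mm)", y = "difference (mm)") +
    ggplot2::theme_minimal()
}

#' Plot an agreement report
#'
#' Draws the Scheffe pairwise mean differences with their simultaneous
#' confidence intervals (the report's most decision-relevant view).
#'
#' @param object An `agreement_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot agreement_report
#' @export
autoplot.agreement_report <- function(object, ...) {
  sch <- object$scheffe
  sch$pair <- paste(sch$method1, "-", sch$method2)
  ggplot2::ggplot(sch, ggplot2::aes(x = .data$diff, y = .data$pair)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_lo,
                                         xmax = .data$ci_hi), height = 0.2) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "mean difference (mm), Scheffe 95% CI", y = NULL) +
    ggplot2::theme_minimal()
}

#' Display an image or mask with measurement overlays
#'
#' Base-graphics quick look: the image as a grey raster, optionally the
#' fitted pupil circle and lid-margin row from a [measure_image()] record.
#'
#' @param image Numeric matrix in `[0, 1]`.
#' @param measurement Optional one-row tibble from [measure_image()].
#' @return Invisibly, `NULL`.
#' @export
plot_eye_image <- function(image, measurement = NULL) {
  op <- graphics::par(mar = c(1, 1, 1, 1)); on.exit(graphics::par(op))
  graphics::plot(c(1, ncol(image)), c(1, nrow(image)), type = "n", asp = 1,
                 axes = FALSE, xlab = "", ylab = "", ylim = c(nrow(image), 1))
  graphics::rasterImage(image, 1, nrow(image), ncol(image), 1)
  if (!is.null(measurement) && isTRUE(measurement$ok)) {
    th <- seq(0, 2 * pi, length.out = 200)
    graphics::lines(measurement$pupil_col_px + measurement$pupil_radius_px * cos(th),
                    measurement$pupil_row_px + measurement$pupil_radius_px * sin(th),
                    col = "red")
    graphics::abline(h = measurement$lid_margin_row_px, col = "cyan")
    graphics::points(measurement$pupil_col_px, measurement$pupil_row_px,
                     col = "red", pch = 3)
  }
  invisible(NULL)
}
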