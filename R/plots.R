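#' Plot an ADC histogram with an optional fitted mixture overlay
#'
#' @param object An `adc_histogram`.
#' @param fit Optional `double_gaussian_fit` to overlay (full mixture plus
#'   the weighted components).
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.adc_histogram <- function(object, fit = NULL, ...) {
  df <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = .data$density)) +
    ggplot2::geom_col(width = object$width, fill = "skyblue3",
                      colour = NA, alpha = 0.8) +
    ggplot2::labs(x = expression(ADC ~ (mu * m^2 / ms)), y = "Density") +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    grid <- seq(min(object$breaks), max(object$breaks), length.out = 400)
    curves <- tibble::tibble(
      x = rep(grid, 3),
      y = c(fit$f * stats::dnorm(grid, fit$mu_L, fit$sigma_L) +
              (1 - fit$f) * stats::dnorm(grid, fit$mu_H, fit$sigma_H),
            fit$f * stats::dnorm(grid, fit$mu_L, fit$sigma_L),
            (1 - fit$f) * stats::dnorm(grid, fit$mu_H, fit$sigma_H)),
      component = rep(c("mixture", "lower (ADC_L)", "higher (ADC_H)"),
                      each = length(grid)))
    p <- p + ggplot2::geom_line(
      data = curves,
      ggplot2::aes(x = .data$x, y = .data$y, colour = .data$component),
      linewidth = 0.7) +
      ggplot2::scale_colour_manual(values = c(
        "mixture" = "black", "lower (ADC_L)" = "blue3",
        "higher (ADC_H)" = "red3"))
  }
  p
}

#' @rdname autoplot.adc_histogram
#' @export
autoplot.double_gaussian_fit <- function(object, ...) {
  if (is.null(object$histogram)) {
    rlang::abort("autoplot: fit carries no histogram; plot via autoplot(hist, fit)")
  }
  autoplot.adc_histogram(object$histogram, fit = object, ...)
}

#' Plot an axial slice of a probability map
#'
#' @param object A `probability_map`.
#' @param slice Axial slice index (third axis); defaults to the slice with
#'   the most defined voxels.
#' @param ... Ignored.
#' @return A ggplot; undefined voxels are blank.
#' @export
autoplot.probability_map <- function(object, slice = NULL, ...) {
  arr <- unclass(object)
  if (is.null(slice)) {
    slice <- which.max(apply(!is.nan(arr), 3, sum))
  }
  sl <- arr[, , slice]
  df <- expand.grid(i = seq_len(nrow(sl)), j = seq_len(ncol(sl)))
  df$index <- as.vector(sl)
  df <- df[!is.nan(df$index), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$j,
                                   fill = .data$index)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "red3", mid = "white",
                                  high = "blue3", limits = c(-1, 1),
                                  name = "P(lower)") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("Probability-index map, slice %d", slice),
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot Kaplan-Meier curves for a two-group comparison
#'
#' @param object A `km_logrank_result`.
#' @param ... Ignored.
#' @return A ggplot of the two survival step functions, annotated with the
#'   log-rank p-value.
#' @export
autoplot.km_logrank_result <- function(object, ...) {
  sf <- object$survfit
  strata <- rep(sub("^g=", "", names(sf$strata)), sf$strata)
  df <- dplyr::bind_rows(lapply(split(
    tibble::tibble(time = sf$time, surv = sf$surv, group = strata),
    strata), function(d) {
      dplyr::bind_rows(tibble::tibble(time = 0, surv = 1,
                                      group = d$group[1]), d)
    }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$surv,
                                   colour = .data$group)) +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (months)", y = "Survival probability",
                  colour = NULL,
                  subtitle = sprintf("log-rank p = %.4g", object$p)) +
    ggplot2::theme_minimal()
}

#' Scatter plot of expression against ADC_L
#'
#' @param data Cohort data frame.
#' @param x,y Columns to plot (tidy-eval); defaults `adcl_true` and
#'   `expression`.
#' @return A ggplot with the least-squares line.
#' @export
plot_expression_adcl <- function(data, x = adcl_true, y = expression) {
  ggplot2::ggplot(data, ggplot2::aes(x = {{ x }}, y = {{ y }})) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "red3") +
    ggplot2::labs(x = expression(ADC[L] ~ (mu * m^2 / ms)),
                  y = "Expression") +
    ggplot2::theme_minimal()
}
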