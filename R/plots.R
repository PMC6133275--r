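# ggplot2 displays for the result types: scree/loadings for the PCA,
# interaction cell-mean plots for the evaluation table, stability bars,
# range-size regression panels and per-species residual plots.

#' @method autoplot vs_pca
#' @export
autoplot.vs_pca <- function(object, ...) {
  d <- tidy(object)
  d$axis_n <- seq_len(nrow(d))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$axis_n, y = .data$eigenvalue)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "red3") +
    ggplot2::labs(x = "Principal axis", y = "Eigenvalue (latent root)",
                  title = "Correlation-matrix PCA scree",
                  subtitle = "dashed: Kaiser-Guttman cut-off") +
    ggplot2::theme_minimal()
}

#' Interaction cell means of an evaluation metric
#'
#' Mean and 95% confidence interval of a metric by predictor set and
#' algorithm, faceted by tolerance class - the standard display for reading
#' how collinearity treatment, algorithm and niche breadth interact.
#'
#' @param object A [run_experiment()] result.
#' @param response Metric column (default `"TSS"`).
#' @param rule Threshold rule (default `"balance"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot vs_eval_table
#' @export
autoplot.vs_eval_table <- function(object, response = "TSS",
                                   rule = "balance", ...) {
  d <- eval_table_factors(object, rule)
  d$.y <- d[[response]]
  cm <- dplyr::summarise(
    dplyr::group_by(d, .data$predictor_set, .data$algorithm,
                    .data$tolerance_class),
    mean = mean(.data$.y, na.rm = TRUE),
    se = sd(.data$.y, na.rm = TRUE) / sqrt(sum(!is.na(.data$.y))),
    .groups = "drop")
  cm$lo <- cm$mean - 1.96 * cm$se
  cm$hi <- cm$mean + 1.96 * cm$se
  ggplot2::ggplot(cm, ggplot2::aes(x = .data$predictor_set, y = .data$mean,
                                   colour = .data$algorithm,
                                   group = .data$algorithm)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lo, ymax = .data$hi)) +
    ggplot2::facet_wrap(~tolerance_class) +
    ggplot2::labs(x = "Predictor set", y = response,
                  title = sprintf("%s by predictor set, algorithm and tolerance (%s threshold)",
                                  response, rule)) +
    ggplot2::theme_minimal()
}

#' @method autoplot vs_stability
#' @export
autoplot.vs_stability <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$predictor_set,
                               y = .data$mean_variance,
                               colour = .data$algorithm,
                               group = .data$algorithm)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_lower,
                                          ymax = .data$ci_upper)) +
    ggplot2::labs(x = "Predictor set",
                  y = "Mean TSS variance across replicates",
                  title = "Model stability under occurrence resampling") +
    ggplot2::theme_minimal()
}

#' @method autoplot vs_range_fit
#' @export
autoplot.vs_range_fit <- function(object, rule = "balance", ...) {
  d <- attr(object, "data")
  d <- d[d$threshold_rule == rule, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$real_range,
                                  y = .data$predicted_range)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "red3", linewidth = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "blue3",
                         linetype = 2) +
    ggplot2::facet_grid(algorithm ~ predictor_set) +
    ggplot2::labs(x = "True range size (cells)",
                  y = "Predicted range size (cells)",
                  title = sprintf("Range-size recovery (%s threshold)", rule),
                  subtitle = "red: fitted OLS; dashed blue: 1:1 line") +
    ggplot2::theme_minimal()
}

#' @method autoplot vs_residuals
#' @export
autoplot.vs_residuals <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$species_id, y = .data$mean_residual,
                               colour = .data$algorithm)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_lower,
                                          ymax = .data$ci_upper),
                             position = ggplot2::position_dodge(width = 0.6),
                             size = 0.3) +
    ggplot2::facet_wrap(~tolerance_class, scales = "free_x") +
    ggplot2::labs(x = "Species", y = "Mean ANCOVA residual",
                  title = "Per-species residual structure (idiosyncrasy)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
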