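#' Plot targeting-outcome distributions by protocol condition
#'
#' Boxplots of NERNI (or target mean En) per protocol condition over a
#' transfer table, the standard view for comparing personalized,
#' group-optimized and template-derived protocols.
#'
#' @param table a transfer table from [evaluate_transfer()].
#' @param metric `"nerni"` or `"mean_en"`.
#' @return a ggplot object.
#' @export
plot_transfer <- function(table, metric = c("nerni", "mean_en")) {
  metric <- match.arg(metric)
  d <- transfer_condition(table)
  d <- d[!is.na(d[[metric]]), ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$condition,
                                  y = .data[[metric]])) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5, size = 1) +
    ggplot2::labs(x = NULL,
                  y = if (metric == "nerni") "NERNI"
                      else expression("target" ~ group("<", E[n], ">") ~ "(V/m)")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot NERNI against target mean En with the quadratic fit
#'
#' @param table a transfer table.
#' @return a ggplot object.
#' @export
plot_nerni_vs_mean_en <- function(table) {
  d <- table[!is.na(table$nerni) & !is.na(table$mean_en), ]
  fit <- nerni_vs_mean_en_fit(d)
  co <- fit$coefficients$estimate
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mean_en, y = .data$nerni,
                                  colour = .data$protocol_kind)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::stat_function(
      fun = function(x) co[1] + co[2] * x + co[3] * x^2,
      colour = "red", linewidth = 0.8) +
    ggplot2::labs(x = expression("target" ~ group("<", E[n], ">") ~ "(V/m)"),
                  y = "NERNI", colour = "protocol") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @exportS3Method ggplot2::autoplot
autoplot.optimization_result <- function(object, ...) {
  d <- tibble::tibble(generation = seq_along(object$history),
                      best_objective = object$history)
  ggplot2::ggplot(d, ggplot2::aes(.data$generation, .data$best_objective)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "generation", y = "best NERNI") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.feature_regression <- function(object, ...) {
  d <- tibble::tibble(fitted = stats::fitted(object$model),
                      observed = stats::fitted(object$model) +
                        stats::resid(object$model))
  ggplot2::ggplot(d, ggplot2::aes(.data$fitted, .data$observed)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::labs(x = "fitted", y = "observed") +
    ggplot2::theme_minimal()
}
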