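#' Plot a risk profile
#'
#' @param object A `ddx_risk_profile`.
#' @param type `"roc"`, `"predictiveness"` (absolute risk against score
#'   quantile) or `"risk"` (risks of both disorders across percentiles).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ddx_risk_profile
#' @export
autoplot.ddx_risk_profile <- function(object, type = c("roc", "predictiveness", "risk"), ...) {
  type <- match.arg(type)
  if (type == "roc") {
    ggplot2::ggplot(object$roc_points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
      ggplot2::geom_path(colour = "#2c7fb8") +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey60") +
      ggplot2::coord_equal() +
      ggplot2::labs(x = "False positive rate", y = "True positive rate",
                    title = sprintf("ROC curve (AUC = %.3f)", object$auc)) +
      ggplot2::theme_minimal()
  } else if (type == "predictiveness") {
    ggplot2::ggplot(object$predictiveness_points,
                    ggplot2::aes(x = .data$quantile, y = .data$risk)) +
      ggplot2::geom_line(colour = "#2c7fb8") +
      ggplot2::geom_hline(yintercept = object$model$K, linetype = 2, colour = "grey60") +
      ggplot2::labs(x = "Score quantile", y = "Absolute risk of the case disorder",
                    title = "Predictiveness curve") +
      ggplot2::theme_minimal()
  } else {
    d <- tidyr::pivot_longer(object$percentile_risk,
                             c("risk_case", "risk_control"),
                             names_to = "disorder", values_to = "risk")
    ggplot2::ggplot(d, ggplot2::aes(x = .data$percentile, y = .data$risk,
                                    colour = .data$disorder)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::scale_colour_manual(values = c(risk_case = "#d95f02", risk_control = "#1b9e77"),
                                   labels = c("first disorder", "second disorder")) +
      ggplot2::labs(x = "Score percentile", y = "Absolute risk", colour = NULL) +
      ggplot2::theme_minimal()
  }
}

#' Plot a threshold curve of forecast score discrimination
#'
#' @param object A `ddx_threshold_curve` from [forecast_auc()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ddx_threshold_curve
#' @export
autoplot.ddx_threshold_curve <- function(object, ...) {
  best <- attr(object, "best")
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(x = .data$threshold, y = .data$auc)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::geom_point() +
    ggplot2::geom_point(data = best, colour = "#d95f02", size = 3) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "p-value threshold", y = "Forecast AUC",
                  title = sprintf("Best threshold %.3g (AUC %.3f)", best$threshold, best$auc)) +
    ggplot2::theme_minimal()
}

#' Plot differential GWAS results
#'
#' @param object A `ddx_differential` from [run_differential()].
#' @param type `"manhattan"` or `"qq"` (on genomic-controlled p-values).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ddx_differential
#' @export
autoplot.ddx_differential <- function(object, type = c("manhattan", "qq"), ...) {
  type <- match.arg(type)
  d <- as_tibble(object)
  if (type == "manhattan") {
    d$index <- seq_len(nrow(d))
    ggplot2::ggplot(d, ggplot2::aes(x = .data$index, y = -log10(.data$p_gc),
                                    colour = factor(chrom_order(.data$chrom) %% 2))) +
      ggplot2::geom_point(size = 0.7, show.legend = FALSE) +
      ggplot2::geom_hline(yintercept = -log10(5e-8), linetype = 2, colour = "#d95f02") +
      ggplot2::scale_colour_manual(values = c("#444444", "#2c7fb8")) +
      ggplot2::labs(x = "SNP", y = expression(-log[10](p[GC]))) +
      ggplot2::theme_minimal()
  } else {
    d <- d[order(d$p_gc), ]
    d$expected <- -log10(stats::ppoints(nrow(d)))
    ggplot2::ggplot(d, ggplot2::aes(x = .data$expected, y = -log10(.data$p_gc))) +
      ggplot2::geom_point(size = 0.7) +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey60") +
      ggplot2::labs(x = "Expected -log10(p)", y = "Observed -log10(p)") +
      ggplot2::theme_minimal()
  }
}
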