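# ggplot2 helpers for the result types. All return ggplot objects so they
# compose with further layers.

#' Protein-size histogram split by QC outcome
#'
#' 10-residue bins of translated feature lengths, coloured by pass/fail -
#' the diagnostic showing that correct and error-prone proteins can overlap
#' in length, which is why the alignment verification step exists.
#'
#' @param summary a `qc_summary`.
#' @return ggplot object.
#' @export
plot_qc_sizes <- function(summary) {
  ggplot2::ggplot(summary$size_histogram,
                  ggplot2::aes(x = .data$bin, y = .data$n_features,
                               fill = .data$outcome)) +
    ggplot2::geom_col(position = "stack", width = 9) +
    ggplot2::labs(x = "protein length (10-residue bins)",
                  y = "features", fill = "QC outcome") +
    ggplot2::theme_minimal()
}

#' Rarefaction curves
#'
#' @param curve tibble from [rarefaction_curve()].
#' @return ggplot object.
#' @export
plot_rarefaction <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$depth,
                                      y = .data$expected_richness,
                                      colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "reads sampled", y = "expected richness") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.congruence_curve <- function(object, ...) {
  fit <- if (nrow(object) >= 2) fit_log_curve(object) else NULL
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$n_added,
                                            y = .data$rf_norm)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "features added", y = "normalized RF distance") +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    p <- p + ggplot2::geom_function(
      fun = function(n) fit$a * log(n) + fit$b, colour = "grey40")
  }
  p
}

#' PERMANOVA grid across methods and metrics
#'
#' Dot plot of p-values per method and distance metric with point size
#' mapped to R-squared and the 0.05 line marked - a quick read of which
#' processing routes report the group effect as significant.
#'
#' @param report a `comparison_report` (or its `$permanova` tibble).
#' @return ggplot object.
#' @export
plot_permanova_grid <- function(report) {
  d <- if (inherits(report, "comparison_report")) report$permanova else report
  ggplot2::ggplot(d, ggplot2::aes(x = .data$method, y = .data$p,
                                  colour = .data$metric, size = .data$R2)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_hline(yintercept = 0.05, linetype = "dashed",
                        colour = "red") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "PERMANOVA p", size = expression(R^2)) +
    ggplot2::theme_minimal()
}

#' Mantel correlation grid across method pairs
#'
#' @param report a `comparison_report` (or its `$mantel` tibble).
#' @return ggplot object.
#' @export
plot_mantel_grid <- function(report) {
  d <- if (inherits(report, "comparison_report")) report$mantel else report
  d$pair <- paste(d$method_a, "vs", d$method_b)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pair, y = .data$r,
                                  fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "Mantel r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
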