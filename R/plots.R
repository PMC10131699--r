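# ggplot2 helpers for the common result types.

#' Plot the grade distribution of an instance set
#'
#' @param instances Instance tibble with a `grade` column.
#' @return A ggplot.
#' @export
plot_grade_distribution <- function(instances) {
  df <- dplyr::count(instances, grade = .data$grade) |>
    dplyr::mutate(label = factor(grade_label(.data$grade),
                                 levels = grade_levels()),
                  pct = 100 * .data$n / sum(.data$n))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$label, y = .data$pct)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "GRADE level", y = "% of bodies of evidence") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.qoe_cv <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$score)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.6) +
    ggplot2::labs(x = NULL, y = "score",
                  title = paste("Cross-validated scores,",
                                object$task$kind)) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.qoe_ablation <- function(object, ...) {
  df <- tidyr::pivot_longer(
    object[object$feature != ".none", ],
    c("d_precision", "d_recall", "d_f1"),
    names_to = "metric", values_to = "delta")
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$feature,
                                                      .data$delta),
                                   y = .data$delta)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::geom_point() +
    ggplot2::coord_flip() +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(x = NULL, y = "change vs no ablation") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.evidencegrader <- function(object, ...) {
  df <- tidyr::pivot_longer(object$log, c("train_loss", "dev_score"),
                            names_to = "series", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~series, scales = "free_y") +
    ggplot2::labs(title = "Training trajectory") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
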