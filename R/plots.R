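# ggplot2 visualisations for the map, ROC and cohort result types.

#' @method autoplot cmr_map
#' @export
autoplot.cmr_map <- function(object, ...) {
  df <- tidyr::expand_grid(row = seq_len(nrow(object$values)),
                           col = seq_len(ncol(object$values)))
  df$value <- object$values[cbind(df$row, df$col)]
  df <- df[object$mask[cbind(df$row, df$col)], ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::scale_fill_viridis_c(na.value = "grey40") +
    ggplot2::labs(fill = paste0(object$kind, " [", object$units, "]"),
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @method autoplot cmr_roc
#' @export
autoplot.cmr_roc <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::annotate("point", x = 1 - object$specificity,
                      y = object$sensitivity, colour = "red", size = 2) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("AUC = %.3f (cutoff %.3g, J = %.3f)",
                                  object$auc, object$cutoff,
                                  object$youden_j)) +
    ggplot2::theme_minimal()
}

#' Group-wise distribution plot for one cohort variable
#'
#' @param cohort Cohort tibble.
#' @param variable Column name (string or bare name).
#' @export
plot_cohort_variable <- function(cohort, variable) {
  var <- rlang::as_name(rlang::ensym(variable))
  df <- cohort[!is.na(cohort[[var]]), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data[[var]],
                                   colour = .data$group)) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.5) +
    ggplot2::geom_jitter(width = 0.12, alpha = 0.7) +
    ggplot2::labs(x = NULL, y = var) +
    ggplot2::guides(colour = "none") +
    ggplot2::theme_minimal()
}
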