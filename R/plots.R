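# ggplot2 graphics for each result type.

#' Log-log box-count plot with the fitted slope
#' @param object An `fd_estimate`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fd_estimate
#' @export
autoplot.fd_estimate <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$log_inv_epsilon, .data$log_n_boxes)) +
    ggplot2::geom_abline(slope = object$db, intercept = object$intercept,
                         linetype = "dashed", colour = "grey40") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = expression(log(1 / epsilon)), y = expression(log(N(epsilon))),
      title = sprintf("Box-counting fit: D_b = %.4f (R² = %.4f)",
                      object$db, object$r_squared)) +
    ggplot2::theme_minimal()
}

#' ROC curve plot
#' @param object A `lesion_roc`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot lesion_roc
#' @export
autoplot.lesion_roc <- function(object, ...) {
  df <- tidy(object)
  df <- tibble(fpr = c(1, 1 - df$specificity, 0),
               tpr = c(1, df$sensitivity, 0))
  ggplot2::ggplot(df, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  title = sprintf("ROC, positive = %s (AUC = %.3f)",
                                  object$positive_label, object$auc)) +
    ggplot2::theme_minimal()
}

#' Cluster scatter in the (diagnosis code, FD) plane
#' @param object A `lesion_kmeans`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot lesion_kmeans
#' @export
autoplot.lesion_kmeans <- function(object, ...) {
  df <- tibble(dx_code = object$features$dx_code,
               fd = object$features$fd,
               cluster = factor(object$assignments$cluster))
  ggplot2::ggplot(df, ggplot2::aes(.data$dx_code, .data$fd,
                                   colour = .data$cluster)) +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.6, size = 0.8) +
    ggplot2::labs(x = "Encoded diagnosis", y = "Fractal dimension",
                  title = sprintf("K-means (k = %d): silhouette = %.3f",
                                  object$k, object$silhouette)) +
    ggplot2::theme_minimal()
}

#' FD distributions by group
#'
#' Violin-and-median view of the per-group FD distributions under a scheme.
#'
#' @param records Lesion records with `diagnosis` and `fd`.
#' @param scheme A [grouping_scheme()], its name, or `NULL` for raw
#'   diagnoses.
#' @return A ggplot.
#' @export
plot_fd_distribution <- function(records, scheme = NULL) {
  grp <- if (is.null(scheme)) {
    dplyr::mutate(as_tibble(records), group = .data$diagnosis)
  } else {
    assign_groups(records, scheme)
  }
  ggplot2::ggplot(grp, ggplot2::aes(.data$group, .data$fd)) +
    ggplot2::geom_violin(fill = "grey85") +
    ggplot2::stat_summary(fun = median, geom = "point", size = 2) +
    ggplot2::labs(x = NULL, y = "Fractal dimension") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
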