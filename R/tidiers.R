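# broom-style tidiers for every fitted object the pipeline produces.

#' Tidy the box-count series of an FD estimate
#' @param x An `fd_estimate`.
#' @param ... Unused.
#' @return Tibble `(epsilon, n_boxes, log_inv_epsilon, log_n_boxes)`.
#' @method tidy fd_estimate
#' @export
tidy.fd_estimate <- function(x, ...) {
  dplyr::mutate(x$series,
                log_inv_epsilon = log(1 / .data$epsilon),
                log_n_boxes = log(.data$n_boxes))
}

#' One-row fit summary of an FD estimate
#' @param x An `fd_estimate`.
#' @param ... Unused.
#' @return Tibble `(db, intercept, r_squared, n_scales, foreground_count)`.
#' @method glance fd_estimate
#' @export
glance.fd_estimate <- function(x, ...) {
  tibble(db = x$db, intercept = x$intercept, r_squared = x$r_squared,
         n_scales = nrow(x$series), foreground_count = x$foreground_count)
}

#' Tidy the operating points of a ROC curve
#' @param x A `lesion_roc`.
#' @param ... Unused.
#' @return Tibble `(threshold, sensitivity, specificity)`.
#' @method tidy lesion_roc
#' @export
tidy.lesion_roc <- function(x, ...) x$points

#' One-row ROC summary
#' @param x A `lesion_roc`.
#' @param ... Unused.
#' @return Tibble `(auc, positive_label, n_pos, n_neg)`.
#' @method glance lesion_roc
#' @export
glance.lesion_roc <- function(x, ...) {
  tibble(auc = x$auc, positive_label = x$positive_label,
         n_pos = x$n_pos, n_neg = x$n_neg)
}

#' Tidy per-group medians of a group comparison
#' @param x A `lesion_group_test`.
#' @param ... Unused.
#' @return Tibble `(group, n, median, ci_lo, ci_hi)`.
#' @method tidy lesion_group_test
#' @export
tidy.lesion_group_test <- function(x, ...) x$groups

#' One-row test summary of a group comparison
#' @param x A `lesion_group_test`.
#' @param ... Unused.
#' @return Tibble `(method, statistic, df, p_value)`.
#' @method glance lesion_group_test
#' @export
glance.lesion_group_test <- function(x, ...) x$test

#' Tidy centroids of a fitted K-means model
#' @param x A `lesion_kmeans`.
#' @param ... Unused.
#' @return Tibble with one row per cluster: centroid coordinates and size.
#' @method tidy lesion_kmeans
#' @export
tidy.lesion_kmeans <- function(x, ...) {
  ctr <- as_tibble(x$centroids)
  ctr$cluster <- seq_len(nrow(ctr))
  sizes <- dplyr::count(x$assignments, .data$cluster, name = "size")
  dplyr::left_join(ctr, sizes, by = "cluster")
}

#' One-row quality summary of a fitted K-means model
#' @param x A `lesion_kmeans`.
#' @param ... Unused.
#' @return Tibble `(k, inertia, silhouette, restarts, seed, scaling)`.
#' @method glance lesion_kmeans
#' @export
glance.lesion_kmeans <- function(x, ...) {
  tibble(k = x$k, inertia = x$inertia, silhouette = x$silhouette,
         restarts = x$restarts, seed = x$seed, scaling = x$scaling)
}

#' Tidy PCA loadings
#' @param x A `lesion_pca`.
#' @param ... Unused.
#' @return Long tibble `(feature, component, loading)`.
#' @method tidy lesion_pca
#' @export
tidy.lesion_pca <- function(x, ...) {
  ld <- as_tibble(x$loadings)
  ld$feature <- rownames(x$loadings)
  tidyr::pivot_longer(ld, -"feature", names_to = "component",
                      values_to = "loading")
}

#' One-row-per-component PCA summary
#' @param x A `lesion_pca`.
#' @param ... Unused.
#' @return Tibble `(component, sdev, explained_variance_fraction)`.
#' @method glance lesion_pca
#' @export
glance.lesion_pca <- function(x, ...) {
  tibble(component = colnames(x$loadings), sdev = x$sdev,
         explained_variance_fraction = x$explained_variance_fraction)
}
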