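# ROC threshold screening of FD as a dichotomous classifier. The positive
# call is strictly-greater-than throughout: a lesion is flagged when its FD
# exceeds the threshold.

#' ROC curve of FD for a two-group scheme
#'
#' Sweeps thresholds over the sorted distinct FD values; at each threshold t
#' the positive call is `fd > t`. The AUC is computed by the trapezoidal
#' rule and equals the Mann-Whitney U statistic divided by
#' `n_pos * n_neg` (midranks for ties), which is asserted internally.
#'
#' @param records Lesion records with `diagnosis` and `fd`.
#' @param scheme A two-group [grouping_scheme()] or its name.
#' @param positive Group label treated as positive (the high-FD class),
#'   e.g. `"malignant"` or `"melanoma"`.
#' @return A `lesion_roc`: `points` tibble
#'   `(threshold, sensitivity, specificity)`, `auc`, `positive_label`,
#'   `n_pos`, `n_neg`. [tidy()] returns the points, [glance()] the AUC row.
#' @export
roc_curve <- function(records, scheme, positive) {
  records <- assign_groups(records, scheme)
  if (!"fd" %in% names(records)) stop_value("`records` must have `fd`.")
  labs <- unique(records$group)
  if (!positive %in% labs) {
    stop_value(paste0("positive label '", positive, "' absent from groups."))
  }
  if (length(labs) < 2L) {
    stop_value("ROC needs both a positive and a negative class.")
  }
  is_pos <- records$group == positive
  fd <- records$fd
  n_pos <- sum(is_pos); n_neg <- sum(!is_pos)
  thr <- sort(unique(fd))
  # counts of observations > t via cumulative sums over the sorted values
  sens <- vapply(thr, function(t) sum(fd[is_pos] > t) / n_pos, numeric(1))
  spec <- vapply(thr, function(t) sum(fd[!is_pos] <= t) / n_neg, numeric(1))
  points <- tibble(threshold = thr, sensitivity = sens, specificity = spec)
  # trapezoid over (FPR, TPR), closing the curve at (0,0) and (1,1)
  fpr <- c(1, 1 - spec, 0)
  tpr <- c(1, sens, 0)
  auc <- sum((tpr[-length(tpr)] + tpr[-1]) / 2 * -diff(fpr))
  u <- sum(rank(c(fd[is_pos], fd[!is_pos]))[seq_len(n_pos)]) -
    n_pos * (n_pos + 1) / 2
  stopifnot(abs(auc - u / (n_pos * n_neg)) < 1e-9)
  structure(list(points = points, auc = auc, positive_label = positive,
                 n_pos = n_pos, n_neg = n_neg,
                 scheme = as_scheme(scheme)$name),
            class = "lesion_roc")
}

#' @export
print.lesion_roc <- function(x, ...) {
  cat(sprintf("<lesion_roc> positive = %s (n = %d vs %d), AUC = %.4f\n",
              x$positive_label, x$n_pos, x$n_neg, x$auc))
  invisible(x)
}

#' Operating point of a ROC curve at a threshold
#'
#' @param roc A `lesion_roc` from [roc_curve()].
#' @param threshold FD cutoff; the positive call is `fd > threshold`.
#' @return One-row tibble `(threshold, sensitivity, specificity, youden)`.
#' @export
roc_operating_point <- function(roc, threshold) {
  p <- roc$points
  at <- p[p$threshold <= threshold, ]
  sens <- if (nrow(at) == 0L) 1 else at$sensitivity[which.max(at$threshold)]
  spec <- if (nrow(at) == 0L) 0 else at$specificity[which.max(at$threshold)]
  tibble(threshold = threshold, sensitivity = sens, specificity = spec,
         youden = sens + spec - 1)
}
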