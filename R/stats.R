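# Rank-based group comparisons over FD: Mann-Whitney for two groups,
# Kruskal-Wallis plus Dunn's pairwise z-tests for more, with
# distribution-free median confidence intervals.

#' Distribution-free confidence interval for a median
#'
#' Binomial order-statistic interval: the bounds are the order statistics at
#' the ranks qbinom(alpha/2, n, 1/2) and qbinom(1 - alpha/2, n, 1/2) + 1.
#'
#' @param x Numeric vector (at least 2 values).
#' @param conf_level Coverage level (default 0.95).
#' @return Named numeric vector `c(median, lo, hi)`.
#' @export
median_ci <- function(x, conf_level = 0.95) {
  n <- length(x)
  if (n < 2L) stop_insufficient_data("median CI needs at least 2 values.")
  s <- sort(x)
  alpha <- 1 - conf_level
  lo <- max(1L, qbinom(alpha / 2, n, 0.5))
  hi <- min(n, qbinom(1 - alpha / 2, n, 0.5) + 1L)
  c(median = median(x), lo = s[lo], hi = s[hi])
}

# Dunn's post hoc z statistics on the pooled Kruskal-Wallis ranks, with tie
# correction; two-sided normal p-values.
dunn_pairwise <- function(fd, group, reference, p_adjust_method = "holm") {
  rk <- rank(fd)
  n <- length(fd)
  ties <- table(rk)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  mean_rank <- tapply(rk, group, mean)
  sizes <- table(group)
  others <- setdiff(names(mean_rank), reference)
  z <- vapply(others, function(g) {
    se <- sqrt((n * (n + 1) / 12 - tie_corr) *
                 (1 / sizes[[reference]] + 1 / sizes[[g]]))
    (mean_rank[[g]] - mean_rank[[reference]]) / se
  }, numeric(1))
  p <- 2 * pnorm(-abs(z))
  tibble(comparison = paste(others, "vs", reference),
         group = others, reference = reference,
         z = unname(z), p_value = unname(p),
         p_adjusted = p.adjust(unname(p), method = p_adjust_method))
}

#' Compare FD distributions across groups
#'
#' With exactly two groups a two-sided Mann-Whitney U test is run; with more,
#' a Kruskal-Wallis test followed by Dunn's pairwise comparisons of every
#' group against `reference`. Per-group medians come with distribution-free
#' binomial order-statistic confidence intervals.
#'
#' @param records Lesion records with `diagnosis` and `fd` columns.
#' @param scheme A [grouping_scheme()], its name, or `NULL` to compare the
#'   raw diagnoses.
#' @param reference Reference group for Dunn's comparisons; defaults to
#'   `"non-metastatic melanoma"` when comparing diagnoses, else the first
#'   group.
#' @param conf_level Confidence level for the median intervals.
#' @param p_adjust_method Multiplicity adjustment for Dunn's p-values
#'   (default `"holm"`; see [stats::p.adjust()]).
#' @return A `lesion_group_test`: list with `$test` (method, statistic,
#'   p_value), `$groups` (n, median and CI per group) and `$pairwise`
#'   (Dunn table, or `NULL` for two groups). [glance()] returns the test row,
#'   [tidy()] the per-group summary.
#' @export
compare_groups <- function(records, scheme = NULL, reference = NULL,
                           conf_level = 0.95, p_adjust_method = "holm") {
  records <- as_tibble(records)
  if (!all(c("diagnosis", "fd") %in% names(records))) {
    stop_value("`records` must have `diagnosis` and `fd` columns.")
  }
  if (is.null(scheme)) {
    records$group <- records$diagnosis
    scheme_name <- "histopathological"
  } else {
    records <- assign_groups(records, scheme)
    scheme_name <- as_scheme(scheme)$name
  }
  sizes <- table(records$group)
  if (length(sizes) < 2L) {
    stop_insufficient_data("need at least two non-empty groups.")
  }
  if (any(sizes < 2L)) {
    stop_insufficient_data(paste0(
      "groups with fewer than 2 records: ",
      paste(names(sizes)[sizes < 2L], collapse = ", ")))
  }
  groups <- dplyr::summarise(
    dplyr::group_by(records, .data$group),
    n = dplyr::n(),
    median = median(.data$fd),
    ci_lo = median_ci(.data$fd, conf_level)[["lo"]],
    ci_hi = median_ci(.data$fd, conf_level)[["hi"]],
    .groups = "drop")
  if (length(sizes) == 2L) {
    ht <- wilcox.test(fd ~ group, data = records, exact = FALSE)
    test <- tibble(method = "Mann-Whitney U",
                   statistic = unname(ht$statistic),
                   df = NA_real_, p_value = ht$p.value)
    pairwise <- NULL
  } else {
    ht <- kruskal.test(fd ~ group, data = records)
    test <- tibble(method = "Kruskal-Wallis",
                   statistic = unname(ht$statistic),
                   df = unname(ht$parameter), p_value = ht$p.value)
    if (is.null(reference)) {
      reference <- if ("non-metastatic melanoma" %in% names(sizes)) {
        "non-metastatic melanoma"
      } else {
        names(sizes)[1]
      }
    }
    if (!reference %in% names(sizes)) {
      stop_value(paste0("reference group not present: ", reference))
    }
    pairwise <- dunn_pairwise(records$fd, records$group, reference,
                              p_adjust_method)
  }
  structure(list(test = test, groups = groups, pairwise = pairwise,
                 scheme = scheme_name, conf_level = conf_level),
            class = "lesion_group_test")
}

#' @export
print.lesion_group_test <- function(x, ...) {
  cat(sprintf("<lesion_group_test> %s on '%s' grouping: statistic %.3f, p = %.3g\n",
              x$test$method, x$scheme, x$test$statistic, x$test$p_value))
  print(x$groups)
  if (!is.null(x$pairwise)) {
    cat("Dunn pairwise comparisons:\n")
    print(x$pairwise)
  }
  invisible(x)
}
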