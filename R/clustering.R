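# Unsupervised stage: label encoding, iterated K-means (best of many seeded
# restarts) over the (diagnosis code, FD) plane, silhouette/inertia quality,
# and per-cluster composition reports.

#' Encode diagnoses as an integer feature alongside FD
#'
#' Labels are coded 0..L-1 in lexicographic order (a bijection, so every code
#' decodes back to its label). The encoded label column plus FD form the
#' two-column feature matrix the clustering stage consumes. Note that
#' clustering on an encoded *diagnosis* leaks label information into an
#' unsupervised method; use `fd_only = TRUE` downstream to cluster on FD
#' alone.
#'
#' @param records Lesion records with `diagnosis` and `fd` (optionally `id`).
#' @param label_col Column to encode (default `"diagnosis"`; use `"group"`
#'   after [assign_groups()] to encode a dichotomy).
#' @return A `lesion_features` object: tibble `(id, label, dx_code, fd)` plus
#'   an `encoder` attribute (tibble `label`, `code`).
#' @export
encode_labels <- function(records, label_col = "diagnosis") {
  records <- as_tibble(records)
  if (nrow(records) == 0L) stop_value("`records` is empty.")
  if (!all(c(label_col, "fd") %in% names(records))) {
    stop_value(paste0("`records` needs columns `", label_col, "` and `fd`."))
  }
  labels <- sort(unique(records[[label_col]]))
  encoder <- tibble(label = labels, code = seq_along(labels) - 1L)
  out <- tibble(
    id = if ("id" %in% names(records)) records$id else
      sprintf("R%06d", seq_len(nrow(records))),
    label = records[[label_col]],
    dx_code = encoder$code[match(records[[label_col]], encoder$label)],
    fd = records$fd)
  structure(out, encoder = encoder, class = c("lesion_features",
                                              class(out)))
}

#' Decode feature codes back to labels
#' @param features A `lesion_features` object.
#' @param codes Integer codes to decode.
#' @return Character labels.
#' @export
decode_labels <- function(features, codes) {
  enc <- attr(features, "encoder")
  enc$label[match(codes, enc$code)]
}

feature_matrix <- function(features, scaling = c("standardized", "none"),
                           fd_only = FALSE) {
  scaling <- match.arg(scaling)
  x <- if (fd_only) cbind(fd = features$fd) else
    cbind(dx_code = features$dx_code, fd = features$fd)
  if (scaling == "standardized") {
    sds <- apply(x, 2, sd)
    if (any(sds == 0)) {
      stop_degenerate_input("zero-variance feature column; cannot standardize.")
    }
    x <- scale(x)
  }
  x
}

# Greedy spread-maximising seeding: first centre drawn uniformly, each later
# centre is the point farthest (min-distance) from those already chosen.
farthest_point_init <- function(x, k) {
  n <- nrow(x)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1L)
  mind <- colSums((t(x) - x[centers[1], ])^2)
  if (k > 1L) for (j in 2:k) {
    centers[j] <- which.max(mind)
    mind <- pmin(mind, colSums((t(x) - x[centers[j], ])^2))
  }
  x[centers, , drop = FALSE]
}

#' Iterated K-means over the (diagnosis code, FD) features
#'
#' Runs Lloyd's algorithm to convergence from `restarts` independent
#' greedy-seeded initialisations and keeps the run with the lowest inertia
#' (total within-cluster sum of squares). The silhouette coefficient of the
#' winning assignment is reported alongside.
#'
#' @param features A `lesion_features` from [encode_labels()].
#' @param k Number of clusters (at least 2, silhouette is undefined below).
#' @param restarts Number of random restarts (default 100).
#' @param seed Integer seed making the whole restart sequence reproducible.
#' @param scaling `"standardized"` (default) z-scores both feature columns
#'   before clustering; `"none"` clusters the raw (code, FD) values, the
#'   behaviour of running K-means straight on label-encoded spreadsheets.
#' @param fd_only Cluster on FD alone, ignoring the encoded label.
#' @return A `lesion_kmeans`: `k`, `centroids`, `assignments` tibble
#'   `(id, cluster)`, `inertia`, `silhouette`, `restarts`, `seed`, `scaling`.
#' @export
kmeans_stage <- function(features, k, restarts = 100L, seed = 1L,
                         scaling = c("standardized", "none"),
                         fd_only = FALSE) {
  scaling <- match.arg(scaling)
  k <- as.integer(k)
  if (k < 2L) stop_value("`k` must be at least 2 (silhouette undefined).")
  x <- feature_matrix(features, scaling, fd_only)
  if (nrow(x) < k) stop_value("fewer rows than clusters.")
  if (nrow(unique(x)) < k) stop_value("fewer distinct rows than clusters.")
  best <- NULL
  with_local_seed(seed, {
    for (r in seq_len(restarts)) {
      init <- farthest_point_init(x, k)
      km <- suppressWarnings(
        kmeans(x, centers = init, iter.max = 300L, algorithm = "Lloyd"))
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
  })
  sil <- silhouette_score(x, best$cluster)
  structure(
    list(k = k, centroids = best$centers,
         assignments = tibble(id = features$id, cluster = best$cluster),
         inertia = best$tot.withinss, silhouette = sil,
         restarts = restarts, seed = seed, scaling = scaling,
         fd_only = fd_only, features = features),
    class = "lesion_kmeans")
}

#' @export
print.lesion_kmeans <- function(x, ...) {
  cat(sprintf(
    "<lesion_kmeans> k = %d (%d restarts): inertia = %.3f, silhouette = %.3f\n",
    x$k, x$restarts, x$inertia, x$silhouette))
  if (!x$fd_only) {
    cat("note: the encoded diagnosis is a clustering feature;",
        "labels inform the clusters.\n")
  }
  invisible(x)
}

#' Mean silhouette coefficient of a clustering
#'
#' For each point, `s = (b - a) / max(a, b)` with `a` the mean Euclidean
#' distance to its own cluster and `b` the smallest mean distance to another
#' cluster; singletons score 0. The returned value is the mean over points.
#'
#' @param x Numeric matrix of features (or a `lesion_features`, which is
#'   converted with its raw columns).
#' @param assignments Integer cluster ids, one per row.
#' @return Mean silhouette in [-1, 1].
#' @export
silhouette_score <- function(x, assignments) {
  if (inherits(x, "lesion_features")) x <- feature_matrix(x, "none")
  cl <- as.integer(factor(assignments))
  ks <- max(cl)
  if (ks < 2L) stop_value("silhouette needs at least two clusters.")
  n <- nrow(x)
  if (length(cl) != n) stop_value("one assignment per row required.")
  d <- as.matrix(dist(x))
  sizes <- tabulate(cl, ks)
  # mean distance from every point to every cluster, n x k
  sums <- vapply(seq_len(ks), function(g) rowSums(d[, cl == g, drop = FALSE]),
                 numeric(n))
  means <- sweep(sums, 2, sizes, "/")
  own <- cl + (seq_len(n) - 1L) * ks  # index into t(means)
  a <- (sums[cbind(seq_len(n), cl)]) / pmax(sizes[cl] - 1L, 1L)
  other <- means
  other[cbind(seq_len(n), cl)] <- Inf
  b <- apply(other, 1, min)
  s <- (b - a) / pmax(a, b)
  s[sizes[cl] == 1L] <- 0
  mean(s)
}

#' Per-cluster composition report
#'
#' Cross-tabulates a fitted clustering against a grouping of the records and
#' reports, per cluster, its size, dominant group and purity (largest group
#' fraction).
#'
#' @param model A `lesion_kmeans` from [kmeans_stage()].
#' @param records The lesion records the model was fitted on (same order).
#' @param scheme A [grouping_scheme()], its name, or `NULL` to report
#'   against the raw diagnoses.
#' @return A tibble `(cluster, size, dominant_group, purity)`.
#' @export
cluster_report <- function(model, records, scheme = NULL) {
  records <- as_tibble(records)
  if (nrow(records) != nrow(model$assignments)) {
    stop_value("`records` and the model cover different row counts.")
  }
  grp <- if (is.null(scheme)) records$diagnosis else
    assign_groups(records, scheme)$group
  df <- tibble(cluster = model$assignments$cluster, group = grp)
  dplyr::summarise(
    dplyr::group_by(df, .data$cluster),
    size = dplyr::n(),
    dominant_group = names(which.max(table(.data$group))),
    purity = max(table(.data$group)) / dplyr::n(),
    .groups = "drop")
}
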