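# PCA stage: eigendecomposition of the correlation structure of the
# standardized feature columns.

#' Principal component analysis of the lesion features
#'
#' Standardizes every feature column and decomposes the correlation
#' structure; components are ordered by explained variance. With the default
#' two-column (diagnosis code, FD) features this summarises how much of the
#' joint spread each orthogonal direction carries.
#'
#' @param features A `lesion_features` from [encode_labels()] or a numeric
#'   matrix/data frame of features.
#' @return A `lesion_pca`: `loadings` (feature x component matrix, columns
#'   orthonormal), `explained_variance_fraction` (sums to 1), `sdev`.
#'   [tidy()] returns the loadings in long form, [glance()] the variance
#'   fractions.
#' @export
pca_stage <- function(features) {
  x <- if (inherits(features, "lesion_features")) {
    cbind(dx_code = features$dx_code, fd = features$fd)
  } else {
    as.matrix(features)
  }
  if (nrow(x) < 2L || ncol(x) < 2L) {
    stop_value("PCA needs at least 2 rows and 2 columns.")
  }
  if (any(apply(x, 2, sd) == 0)) {
    stop_degenerate_input("zero-variance feature column; PCA undefined.")
  }
  pc <- prcomp(x, center = TRUE, scale. = TRUE)
  ev <- pc$sdev^2
  structure(list(loadings = pc$rotation,
                 explained_variance_fraction = ev / sum(ev),
                 sdev = pc$sdev),
            class = "lesion_pca")
}

#' @export
print.lesion_pca <- function(x, ...) {
  cat("<lesion_pca> explained variance fractions:",
      paste(sprintf("%.3f", x$explained_variance_fraction), collapse = ", "),
      "\n")
  invisible(x)
}
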