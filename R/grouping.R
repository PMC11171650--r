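# Diagnosis -> group mapping for the three classification schemes.

benign_labels <- c("nevus", "verrucous lesion", "vascular lesion",
                   "neurofibroma")
melanoma_labels <- c("non-metastatic melanoma", "metastatic melanoma",
                     "Breslow 1", "Breslow 2", "Breslow 3")

#' Build a diagnosis-grouping scheme
#'
#' Three schemes map the 12-diagnosis vocabulary onto clinical dichotomies:
#'
#' * `benign_malignant`: benign = nevi, verrucous (wart) lesions, vascular
#'   lesions and neurofibromas; malignant = melanomas (including the
#'   Breslow-graded lesions), atypical melanocytic proliferations, basal cell
#'   carcinomas and squamous cell carcinomas. Squamous cell carcinoma is
#'   counted malignant; set `scc_malignant = FALSE` to override.
#' * `melanoma_nonmelanoma`: the melanoma group is the melanocytic
#'   malignancies - non-metastatic and metastatic melanoma plus Breslow
#'   1/2/3; everything else is non-melanoma.
#' * `metastatic_nonmetastatic`: defined over the melanoma group only.
#'
#' @param name Scheme name.
#' @param scc_malignant Whether squamous cell carcinoma maps to malignant in
#'   `benign_malignant` (default `TRUE`).
#' @return A `grouping_scheme`: list with `name`, `mapping` (named character
#'   vector diagnosis -> group) and `levels`.
#' @export
grouping_scheme <- function(name = c("benign_malignant",
                                     "melanoma_nonmelanoma",
                                     "metastatic_nonmetastatic"),
                            scc_malignant = TRUE) {
  name <- match.arg(name)
  vocab <- lesion_diagnoses()
  mapping <- switch(
    name,
    benign_malignant = {
      m <- ifelse(vocab %in% benign_labels, "benign", "malignant")
      if (!scc_malignant) m[vocab == "squamous cell carcinoma"] <- "benign"
      setNames(m, vocab)
    },
    melanoma_nonmelanoma = {
      setNames(ifelse(vocab %in% melanoma_labels, "melanoma", "non-melanoma"),
               vocab)
    },
    metastatic_nonmetastatic = {
      setNames(ifelse(melanoma_labels == "metastatic melanoma", "metastatic",
                      "non-metastatic"),
               melanoma_labels)
    })
  structure(list(name = name, mapping = mapping,
                 levels = sort(unique(unname(mapping)))),
            class = "grouping_scheme")
}

#' @export
print.grouping_scheme <- function(x, ...) {
  cat(sprintf("<grouping_scheme> %s: %d diagnoses -> {%s}\n", x$name,
              length(x$mapping), paste(x$levels, collapse = ", ")))
  invisible(x)
}

as_scheme <- function(scheme) {
  if (inherits(scheme, "grouping_scheme")) scheme else grouping_scheme(scheme)
}

#' Assign every lesion record to its group
#'
#' @param records Data frame of lesion records with a `diagnosis` column
#'   (and typically `id` and `fd`).
#' @param scheme A [grouping_scheme()] or its name.
#' @return `records` as a tibble with a `group` column appended.
#' @export
assign_groups <- function(records, scheme) {
  scheme <- as_scheme(scheme)
  records <- as_tibble(records)
  if (!"diagnosis" %in% names(records)) {
    stop_value("`records` must have a `diagnosis` column.")
  }
  unknown <- setdiff(unique(records$diagnosis), names(scheme$mapping))
  if (length(unknown) > 0L) {
    stop_vocabulary(paste0("diagnosis not in the '", scheme$name,
                           "' vocabulary: ",
                           paste(unknown, collapse = ", ")))
  }
  dplyr::mutate(records, group = unname(scheme$mapping[.data$diagnosis]))
}

#' Group sizes under a scheme
#'
#' @inheritParams assign_groups
#' @param weights Optional column name holding per-row counts (so a
#'   per-diagnosis count table can be fed directly, e.g.
#'   [isic_diagnosis_counts()] with `weights = "n"`).
#' @return A tibble `(group, n)`; `n` sums to the number of records (or the
#'   total weight).
#' @examples
#' group_counts(isic_diagnosis_counts(), "benign_malignant", weights = "n")
#' @export
group_counts <- function(records, scheme, weights = NULL) {
  if (nrow(records) == 0L) return(tibble(group = character(), n = integer()))
  grouped <- assign_groups(records, scheme)
  if (is.null(weights)) {
    dplyr::count(grouped, .data$group, name = "n")
  } else {
    dplyr::summarise(dplyr::group_by(grouped, .data$group),
                     n = sum(.data[[weights]]), .groups = "drop")
  }
}
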