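# Reference cohort composition and the default simulation spec.

#' The 12-diagnosis controlled vocabulary
#'
#' Histopathological diagnoses recognised by the grouping schemes, in
#' lexicographic order.
#'
#' @return Character vector of 12 diagnosis labels.
#' @export
lesion_diagnoses <- function() {
  sort(c("non-metastatic melanoma", "metastatic melanoma",
         "atypical melanocytic proliferation", "nevus", "verrucous lesion",
         "vascular lesion", "squamous cell carcinoma", "neurofibroma",
         "basal cell carcinoma", "Breslow 1", "Breslow 2", "Breslow 3"))
}

#' Composition of the curated ISIC dermatoscopy cohort
#'
#' Per-diagnosis image counts of the 39,270-lesion ISIC gallery cohort used
#' to develop the fractal-dimension screen. These counts are the input for
#' reproducing the published group totals via [group_counts()].
#'
#' @return A tibble with columns `diagnosis` and `n` (12 rows, summing to
#'   39,270).
#' @export
isic_diagnosis_counts <- function() {
  tibble(
    diagnosis = c("non-metastatic melanoma", "metastatic melanoma",
                  "atypical melanocytic proliferation", "nevus",
                  "verrucous lesion", "vascular lesion",
                  "squamous cell carcinoma", "neurofibroma",
                  "basal cell carcinoma", "Breslow 1", "Breslow 2",
                  "Breslow 3"),
    n = c(5858L, 4L, 99L, 28778L, 6L, 259L, 687L, 7L, 3399L, 150L, 14L, 9L))
}

#' Default cohort-simulation spec mimicking the ISIC cohort
#'
#' One row per diagnosis with the class size (the ISIC cohort composition
#' scaled by `scale`, rounded up so the rarest class survives), a target
#' median FD, and the FD spread. The five medians reported for the reference
#' cohort (melanoma-family 1.755, Breslow 3 1.859, atypical melanocytic
#' proliferation 1.636, and group aggregates near 1.74/1.651) anchor the
#' per-class targets; unreported classes get values consistent with those
#' aggregates. Spread defaults to 0.08 FD units for every class.
#'
#' @param scale Multiplier applied to the reference class sizes (default 0.1).
#' @param sd_fd FD standard deviation used for every class.
#' @return A tibble with columns `label`, `n`, `median_fd`, `sd_fd`, usable
#'   directly by [make_cohort()].
#' @export
default_cohort_spec <- function(scale = 0.1, sd_fd = 0.08) {
  counts <- isic_diagnosis_counts()
  med <- c("non-metastatic melanoma" = 1.755,
           "metastatic melanoma" = 1.755,
           "atypical melanocytic proliferation" = 1.636,
           "nevus" = 1.645,
           "verrucous lesion" = 1.660,
           "vascular lesion" = 1.660,
           "squamous cell carcinoma" = 1.700,
           "neurofibroma" = 1.660,
           "basal cell carcinoma" = 1.700,
           "Breslow 1" = 1.760,
           "Breslow 2" = 1.800,
           "Breslow 3" = 1.859)
  tibble(label = counts$diagnosis,
         n = as.integer(ceiling(counts$n * scale)),
         median_fd = unname(med[counts$diagnosis]),
         sd_fd = sd_fd)
}
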