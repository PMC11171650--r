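# Two-stage FD decision rule: stage 1 flags malignancy, stage 2 (reached
# only by malignant calls) flags melanoma. Both stages use a
# strictly-greater-than cutoff on FD.

#' Apply the two-stage FD decision rule
#'
#' Stage 1 calls a lesion malignant when `fd > t_malignant`; for malignant
#' calls, stage 2 calls melanoma when `fd > t_melanoma` (both strict).
#' Benign calls have no stage-2 outcome. The melanoma cutoff defaults to
#' 1.755, the melanoma-group median FD of the reference cohort; the
#' malignancy cutoff defaults to 1.74, the malignant-group median, and should
#' be tuned to the local operating point.
#'
#' @param fd Numeric vector of fractal dimensions in (0, 2.1).
#' @param t_malignant Stage-1 cutoff, in (1, 2); default 1.74.
#' @param t_melanoma Stage-2 cutoff, in (1, 2); default 1.755.
#' @return A tibble `(fd, stage1, stage2, t_malignant, t_melanoma)` with
#'   `stage1` in {benign, malignant} and `stage2` in
#'   {melanoma, non-melanoma, NA}.
#' @examples
#' decide_lesion(c(1.90, 1.755, 1.60), t_malignant = 1.70)
#' @export
decide_lesion <- function(fd, t_malignant = 1.74, t_melanoma = 1.755) {
  if (any(!is.finite(fd)) || any(fd <= 0 | fd >= 2.1)) {
    stop_value("`fd` values must lie in (0, 2.1).")
  }
  for (t in c(t_malignant, t_melanoma)) {
    if (t <= 1 || t >= 2) stop_value("thresholds must lie in (1, 2).")
  }
  malignant <- fd > t_malignant
  stage2 <- ifelse(malignant,
                   ifelse(fd > t_melanoma, "melanoma", "non-melanoma"),
                   NA_character_)
  tibble(fd = fd,
         stage1 = ifelse(malignant, "malignant", "benign"),
         stage2 = stage2,
         t_malignant = t_malignant, t_melanoma = t_melanoma)
}

confusion_row <- function(truth_pos, call_pos, stage, threshold) {
  tp <- sum(truth_pos & call_pos); fn <- sum(truth_pos & !call_pos)
  tn <- sum(!truth_pos & !call_pos); fp <- sum(!truth_pos & call_pos)
  tibble(stage = stage, threshold = threshold,
         sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
         tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Screen a cohort with the two-stage decision rule
#'
#' Applies [decide_lesion()] to every record and scores each stage against
#' the histopathological truth: stage 1 against the benign/malignant
#' grouping, stage 2 against melanoma/non-melanoma.
#'
#' @param records Lesion records with `diagnosis` and `fd`.
#' @param t_malignant,t_melanoma Cutoffs as in [decide_lesion()].
#' @return A two-row tibble, one per stage:
#'   `(stage, threshold, sensitivity, specificity, tp, fp, tn, fn)`.
#' @export
screen_cohort <- function(records, t_malignant = 1.74, t_melanoma = 1.755) {
  records <- as_tibble(records)
  if (nrow(records) == 0L) stop_insufficient_data("empty cohort.")
  calls <- decide_lesion(records$fd, t_malignant, t_melanoma)
  truth1 <- assign_groups(records, "benign_malignant")$group == "malignant"
  truth2 <- assign_groups(records, "melanoma_nonmelanoma")$group == "melanoma"
  dplyr::bind_rows(
    confusion_row(truth1, calls$stage1 == "malignant", "malignant_vs_benign",
                  t_malignant),
    confusion_row(truth2, records$fd > t_melanoma, "melanoma_vs_nonmelanoma",
                  t_melanoma))
}
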