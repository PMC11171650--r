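# Grouping schemes, comparative statistics, ROC and the two-stage rule.

test_that("the reference cohort counts reproduce every published group total", {
  counts <- isic_diagnosis_counts()
  bm <- group_counts(counts, "benign_malignant", weights = "n")
  expect_identical(bm$n[bm$group == "benign"], 29050L)
  expect_identical(bm$n[bm$group == "malignant"], 10220L)
  mn <- group_counts(counts, "melanoma_nonmelanoma", weights = "n")
  expect_identical(mn$n[mn$group == "melanoma"], 6035L)
  expect_identical(mn$n[mn$group == "non-melanoma"], 33235L)
  mel <- dplyr::filter(assign_groups(counts, "melanoma_nonmelanoma"),
                       group == "melanoma")
  mm <- group_counts(mel, "metastatic_nonmetastatic", weights = "n")
  expect_identical(mm$n[mm$group == "metastatic"], 4L)
  expect_identical(mm$n[mm$group == "non-metastatic"], 6031L)
})

test_that("grouping is total, partition-preserving, and catches unknowns", {
  cohort <- make_cohort(default_cohort_spec(scale = 0.02), seed = 2)
  for (nm in c("benign_malignant", "melanoma_nonmelanoma")) {
    grouped <- assign_groups(cohort, nm)
    expect_false(any(is.na(grouped$group)))
    expect_identical(sum(group_counts(cohort, nm)$n), nrow(cohort))
  }
  expect_identical(
    assign_groups(tibble::tibble(diagnosis = "Breslow 1", fd = 1.8),
                  "melanoma_nonmelanoma")$group, "melanoma")
  expect_identical(
    assign_groups(tibble::tibble(diagnosis = "nevus", fd = 1.6),
                  "benign_malignant")$group, "benign")
  expect_error(
    assign_groups(tibble::tibble(diagnosis = "unknown-lesion", fd = 1.5),
                  "benign_malignant"),
    class = "lesionfd_vocabulary_error")
  # squamous cell carcinoma override flips the malignant total
  scheme2 <- grouping_scheme("benign_malignant", scc_malignant = FALSE)
  bm2 <- group_counts(isic_diagnosis_counts(), scheme2, weights = "n")
  expect_identical(bm2$n[bm2$group == "malignant"], 10220L - 687L)
  expect_identical(group_counts(tibble::tibble(diagnosis = character(),
                                               fd = numeric()),
                                "benign_malignant")$n, integer())
})

test_that("two separated groups are detected, identical groups are not", {
  cohort <- mw_cohort(n = 300, seed = 5)
  res <- compare_groups(cohort, "melanoma_nonmelanoma")
  expect_identical(res$test$method, "Mann-Whitney U")
  expect_lt(res$test$p_value, 1e-6)
  expect_null(res$pairwise)
  med <- tidy(res)
  expect_true(all(med$ci_lo <= med$median & med$median <= med$ci_hi))
  # extreme separation: 10 sd apart
  far <- tibble::tibble(
    diagnosis = rep(c("nevus", "non-metastatic melanoma"), each = 50),
    fd = c(rnorm(50, 1.3, 0.02), rnorm(50, 1.9, 0.02)))
  expect_lt(glance(compare_groups(far, "melanoma_nonmelanoma"))$p_value, 1e-6)
})

test_that("multi-group comparison runs Kruskal-Wallis with Dunn post hocs", {
  cohort <- make_cohort(default_cohort_spec(scale = 0.05), seed = 3)
  cohort <- dplyr::filter(
    cohort, !diagnosis %in% c("metastatic melanoma", "verrucous lesion",
                              "neurofibroma", "Breslow 2", "Breslow 3"))
  res <- compare_groups(cohort)
  expect_identical(res$test$method, "Kruskal-Wallis")
  expect_lt(res$test$p_value, 1e-6)
  expect_identical(unique(res$pairwise$reference), "non-metastatic melanoma")
  expect_identical(nrow(res$pairwise), length(unique(cohort$diagnosis)) - 1L)
  expect_true(all(res$pairwise$p_adjusted >= res$pairwise$p_value - 1e-15))
  # nevus sits far from melanoma in the default spec
  expect_lt(res$pairwise$p_adjusted[res$pairwise$group == "nevus"], 1e-4)
})

test_that("insufficient groups raise typed errors", {
  one <- tibble::tibble(diagnosis = rep("nevus", 5), fd = runif(5, 1.5, 1.7))
  expect_error(compare_groups(one, "benign_malignant"),
               class = "lesionfd_insufficient_data_error")
  tiny <- tibble::tibble(diagnosis = c(rep("nevus", 5), "Breslow 3"),
                         fd = runif(6, 1.5, 1.7))
  expect_error(compare_groups(tiny, "benign_malignant"),
               class = "lesionfd_insufficient_data_error")
})

test_that("median CI follows the binomial order-statistic construction", {
  withr::with_seed(17, x <- rnorm(41))
  ci <- median_ci(x, 0.95)
  s <- sort(x)
  expect_identical(ci[["lo"]], s[qbinom(0.025, 41, 0.5)])
  expect_identical(ci[["hi"]], s[qbinom(0.975, 41, 0.5) + 1])
  expect_identical(ci[["median"]], median(x))
})

test_that("ROC sweeps distinct thresholds with a strict-greater rule", {
  rec <- tibble::tibble(
    diagnosis = rep(c("non-metastatic melanoma", "nevus"), each = 3),
    fd = c(1.6, 1.7, 1.9, 1.2, 1.4, 1.5))
  roc <- roc_curve(rec, "melanoma_nonmelanoma", positive = "melanoma")
  expect_equal(roc$auc, 1.0)
  expect_identical(nrow(roc$points), 6L)
  expect_true(all(diff(roc$points$sensitivity) <= 0))
  rec$fd <- c(1.4, 1.5, 1.9, 1.2, 1.6, 1.7)
  roc2 <- roc_curve(rec, "melanoma_nonmelanoma", positive = "melanoma")
  expect_equal(roc2$auc, 5 / 9, tolerance = 1e-12)
  expect_equal(roc2$auc, brute_auc(c(1.4, 1.5, 1.9), c(1.2, 1.6, 1.7)),
               tolerance = 1e-12)
})

test_that("trapezoid AUC equals the Mann-Whitney U form, ties included", {
  withr::with_seed(23, {
    for (i in 1:5) {
      rec <- mw_cohort(n = 200, seed = i)
      rec$fd <- round(rec$fd, sample(1:3, 1))  # force ties
      roc <- roc_curve(rec, "melanoma_nonmelanoma", positive = "melanoma")
      pos <- rec$fd[assign_groups(rec, "melanoma_nonmelanoma")$group ==
                      "melanoma"]
      neg <- rec$fd[assign_groups(rec, "melanoma_nonmelanoma")$group !=
                      "melanoma"]
      u <- sum(rank(c(pos, neg))[seq_along(pos)]) -
        length(pos) * (length(pos) + 1) / 2
      expect_equal(roc$auc, u / (length(pos) * length(neg)),
                   tolerance = 1e-9)
    }
  })
})

test_that("ROC agrees with pROC on a seeded cohort", {
  skip_if_not_installed("pROC")
  rec <- mw_cohort(n = 400, seed = 31)
  grouped <- assign_groups(rec, "melanoma_nonmelanoma")
  roc <- roc_curve(rec, "melanoma_nonmelanoma", positive = "melanoma")
  ref <- suppressMessages(pROC::auc(
    pROC::roc(grouped$group == "melanoma", grouped$fd, direction = "<")))
  expect_equal(roc$auc, as.numeric(ref), tolerance = 1e-9)
})

test_that("single-class input cannot form a ROC curve", {
  rec <- tibble::tibble(diagnosis = rep("nevus", 10), fd = runif(10, 1.4, 1.8))
  expect_error(roc_curve(rec, "melanoma_nonmelanoma", positive = "melanoma"),
               class = "lesionfd_value_error")
})

test_that("the two-stage rule applies strict thresholds in order", {
  out <- decide_lesion(c(1.90, 1.755, 1.60), t_malignant = 1.70)
  expect_identical(out$stage1, c("malignant", "malignant", "benign"))
  expect_identical(out$stage2, c("melanoma", "non-melanoma", NA))
  expect_error(decide_lesion(2.2), class = "lesionfd_value_error")
  expect_error(decide_lesion(1.8, t_malignant = 0.9),
               class = "lesionfd_value_error")
})

test_that("raising fd never demotes a decision (monotonicity)", {
  fds <- seq(1.05, 2.05, by = 0.01)
  out <- decide_lesion(fds)
  expect_true(all(diff(out$stage1 == "malignant") >= 0))
  mel <- !is.na(out$stage2) & out$stage2 == "melanoma"
  expect_true(all(diff(mel) >= 0))
})

test_that("screening matches a brute-force counting oracle", {
  cohort <- make_cohort(default_cohort_spec(), seed = 19)
  sc <- screen_cohort(cohort, t_malignant = 1.74, t_melanoma = 1.755)
  truth_mal <- assign_groups(cohort, "benign_malignant")$group == "malignant"
  truth_mel <- assign_groups(cohort, "melanoma_nonmelanoma")$group == "melanoma"
  expect_equal(sc$sensitivity[sc$stage == "malignant_vs_benign"],
               sum(cohort$fd > 1.74 & truth_mal) / sum(truth_mal))
  expect_equal(sc$specificity[sc$stage == "malignant_vs_benign"],
               sum(cohort$fd <= 1.74 & !truth_mal) / sum(!truth_mal))
  expect_equal(sc$sensitivity[sc$stage == "melanoma_vs_nonmelanoma"],
               sum(cohort$fd > 1.755 & truth_mel) / sum(truth_mel))
  expect_equal(sc$specificity[sc$stage == "melanoma_vs_nonmelanoma"],
               sum(cohort$fd <= 1.755 & !truth_mel) / sum(!truth_mel))
  # perfect separation scores perfectly
  sep <- tibble::tibble(
    diagnosis = rep(c("nevus", "non-metastatic melanoma"), each = 20),
    fd = c(runif(20, 1.2, 1.5), runif(20, 1.8, 1.95)))
  sc2 <- screen_cohort(sep, t_malignant = 1.6, t_melanoma = 1.6)
  expect_true(all(sc2$sensitivity == 1 & sc2$specificity == 1))
  expect_error(screen_cohort(sep[0, ]),
               class = "lesionfd_insufficient_data_error")
})

test_that("roc_operating_point reads the curve at arbitrary cutoffs", {
  rec <- mw_cohort(n = 300, seed = 11)
  roc <- roc_curve(rec, "melanoma_nonmelanoma", positive = "melanoma")
  op <- roc_operating_point(roc, 1.755)
  truth <- assign_groups(rec, "melanoma_nonmelanoma")$group == "melanoma"
  expect_equal(op$sensitivity, sum(rec$fd > 1.755 & truth) / sum(truth))
  expect_equal(op$specificity, sum(rec$fd <= 1.755 & !truth) / sum(!truth))
})
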