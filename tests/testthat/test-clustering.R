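# Label encoding, iterated K-means, silhouette, PCA, cluster reports.

two_blob_records <- function(n = 50) {
  tibble::tibble(
    id = sprintf("B%03d", seq_len(2 * n)),
    diagnosis = rep(c("nevus", "non-metastatic melanoma"), each = n),
    fd = c(rnorm(n, 1.2, 0.005), rnorm(n, 1.9, 0.005)))
}

test_that("label encoding is a lexicographic bijection that round-trips", {
  rec <- tibble::tibble(diagnosis = c("malignant", "benign", "malignant"),
                        fd = c(1.8, 1.6, 1.75))
  f <- encode_labels(rec)
  expect_identical(f$dx_code, c(1L, 0L, 1L))
  enc <- attr(f, "encoder")
  expect_identical(enc$label, c("benign", "malignant"))
  full <- encode_labels(tibble::tibble(diagnosis = lesion_diagnoses(),
                                       fd = seq(1.5, 1.9, length.out = 12)))
  expect_identical(sort(unique(full$dx_code)), 0:11)
  expect_identical(decode_labels(full, full$dx_code), full$label)
})

test_that("k-means finds degenerate clusters exactly", {
  rec <- tibble::tibble(diagnosis = rep(c("a", "b"), each = 50),
                        fd = rep(c(0.5, 1.5), each = 50))
  f <- encode_labels(rec)
  withr::with_seed(1, {
    m <- kmeans_stage(f, k = 2, restarts = 5, seed = 3, scaling = "none")
  })
  expect_equal(m$inertia, 0)
  expect_equal(m$silhouette, 1)
  expect_identical(length(unique(m$assignments$cluster)), 2L)
})

test_that("k-means validates k and the row count", {
  rec <- two_blob_records(5)
  f <- encode_labels(rec)
  expect_error(kmeans_stage(f, k = 1, seed = 1),
               class = "lesionfd_value_error")
  expect_error(kmeans_stage(f, k = 11, seed = 1),
               class = "lesionfd_value_error")
  same <- encode_labels(tibble::tibble(diagnosis = rep("x", 10), fd = 1.5))
  expect_error(kmeans_stage(same, k = 3, seed = 1, scaling = "none"),
               class = "lesionfd_value_error")
})

test_that("every centroid is the mean of its members (Lloyd fixed point)", {
  withr::with_seed(9, rec <- two_blob_records(40))
  f <- encode_labels(rec)
  m <- kmeans_stage(f, k = 2, restarts = 10, seed = 2)
  x <- scale(cbind(f$dx_code, f$fd))
  for (g in seq_len(m$k)) {
    members <- x[m$assignments$cluster == g, , drop = FALSE]
    expect_equal(unname(m$centroids[g, ]), unname(colMeans(members)),
                 tolerance = 1e-9)
  }
  expect_equal(m$inertia, brute_inertia(x, m$assignments$cluster),
               tolerance = 1e-9)
})

test_that("k-means is deterministic under its seed and improves with restarts", {
  withr::with_seed(4, rec <- make_cohort(default_cohort_spec(0.02), seed = 6))
  grouped <- assign_groups(rec, "benign_malignant")
  f <- encode_labels(grouped, label_col = "group")
  m1 <- kmeans_stage(f, k = 3, restarts = 20, seed = 5)
  m2 <- kmeans_stage(f, k = 3, restarts = 20, seed = 5)
  expect_identical(m1$assignments, m2$assignments)
  expect_identical(m1$inertia, m2$inertia)
  single <- kmeans_stage(f, k = 3, restarts = 1, seed = 5)
  expect_lte(m1$inertia, single$inertia + 1e-12)
})

test_that("inertia is non-increasing in k", {
  withr::with_seed(8, rec <- make_cohort(default_cohort_spec(0.02), seed = 9))
  f <- encode_labels(rec)
  inertias <- vapply(2:5, function(k)
    kmeans_stage(f, k = k, restarts = 20, seed = 7)$inertia, numeric(1))
  expect_true(all(diff(inertias) <= 1e-9))
})

test_that("silhouette matches the brute-force oracle to 1e-12", {
  withr::with_seed(14, {
    for (i in 1:5) {
      n <- sample(12:50, 1)
      x <- cbind(runif(n), runif(n))
      cl <- sample(1:3, n, replace = TRUE)
      if (length(unique(cl)) < 2) cl[1:2] <- c(1L, 2L)
      expect_equal(silhouette_score(x, cl), brute_silhouette(x, cl),
                   tolerance = 1e-12)
    }
  })
})

test_that("silhouette agrees with cluster::silhouette", {
  skip_if_not_installed("cluster")
  withr::with_seed(15, {
    x <- cbind(c(rnorm(30, 0), rnorm(30, 3)), c(rnorm(30, 0), rnorm(30, 3)))
    cl <- rep(1:2, each = 30)
    ref <- mean(cluster::silhouette(cl, dist(x))[, "sil_width"])
    expect_equal(silhouette_score(x, cl), ref, tolerance = 1e-12)
  })
})

test_that("silhouette behaves at the separability extremes", {
  withr::with_seed(16, {
    tight <- rbind(cbind(rnorm(40, 0, 0.01), rnorm(40, 0, 0.01)),
                   cbind(rnorm(40, 5, 0.01), rnorm(40, 5, 0.01)))
    expect_gt(silhouette_score(tight, rep(1:2, each = 40)), 0.9)
    homog <- cbind(runif(500), runif(500))
    expect_lt(abs(silhouette_score(homog, sample(1:2, 500, TRUE))), 0.05)
    expect_error(silhouette_score(tight, rep(1, 80)),
                 class = "lesionfd_value_error")
  })
})

test_that("PCA explains perfectly correlated columns with one component", {
  withr::with_seed(20, {
    a <- rnorm(100)
    p <- pca_stage(cbind(a, 2 * a + 3))
    expect_equal(p$explained_variance_fraction[1], 1, tolerance = 1e-9)
    expect_equal(sum(p$explained_variance_fraction), 1, tolerance = 1e-9)
  })
})

test_that("PCA loadings are orthonormal and match the eigen oracle", {
  withr::with_seed(22, {
    for (i in 1:5) {
      x <- matrix(rnorm(100), 50, 2)
      p <- pca_stage(x)
      expect_equal(crossprod(p$loadings), diag(2), tolerance = 1e-9,
                   ignore_attr = TRUE)
      ev <- eigen(stats::cor(x))
      for (j in 1:2) {
        dot <- abs(sum(p$loadings[, j] * ev$vectors[, j]))
        expect_equal(dot, 1, tolerance = 1e-9)
      }
      expect_equal(p$explained_variance_fraction,
                   ev$values / sum(ev$values), tolerance = 1e-9)
    }
  })
})

test_that("constant columns are degenerate for PCA", {
  expect_error(pca_stage(cbind(rep(1, 10), rnorm(10))),
               class = "lesionfd_degenerate_input_error")
})

test_that("cluster reports give perfect purity on separable cohorts", {
  withr::with_seed(26, rec <- two_blob_records(40))
  grouped <- assign_groups(rec, "melanoma_nonmelanoma")
  f <- encode_labels(grouped, label_col = "group")
  m <- kmeans_stage(f, k = 2, restarts = 10, seed = 3)
  rep <- cluster_report(m, rec, "melanoma_nonmelanoma")
  expect_identical(nrow(rep), 2L)
  expect_true(all(rep$purity == 1))
  expect_identical(sort(rep$dominant_group), c("melanoma", "non-melanoma"))
})

test_that("tidiers summarise fitted models", {
  withr::with_seed(28, rec <- two_blob_records(30))
  f <- encode_labels(rec)
  m <- kmeans_stage(f, k = 2, restarts = 5, seed = 4)
  expect_identical(sum(tidy(m)$size), 60L)
  gl <- glance(m)
  expect_identical(gl$k, 2L)
  expect_true(gl$silhouette > 0.5)
  p <- pca_stage(f)
  expect_identical(nrow(tidy(p)), 4L)   # 2 features x 2 components
  expect_equal(sum(glance(p)$explained_variance_fraction), 1,
               tolerance = 1e-9)
})
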