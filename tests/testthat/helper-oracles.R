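# Independent oracles: deliberately naive implementations the fast paths are
# checked against.

# Box counting by explicit double loop over grid cells.
naive_count_boxes <- function(mask, epsilon, grid_offset = c(0L, 0L)) {
  m <- unclass(mask)
  nr <- nrow(m); nc <- ncol(m)
  # grid cells cover [off + k*eps, off + (k+1)*eps) in 0-based coords
  kr_range <- floor((0 - grid_offset[1]) / epsilon):
    floor((nr - 1 - grid_offset[1]) / epsilon)
  kc_range <- floor((0 - grid_offset[2]) / epsilon):
    floor((nc - 1 - grid_offset[2]) / epsilon)
  n <- 0L
  for (kr in kr_range) {
    r0 <- max(1L, grid_offset[1] + kr * epsilon + 1L)
    r1 <- min(nr, grid_offset[1] + (kr + 1L) * epsilon)
    if (r0 > r1) next
    for (kc in kc_range) {
      c0 <- max(1L, grid_offset[2] + kc * epsilon + 1L)
      c1 <- min(nc, grid_offset[2] + (kc + 1L) * epsilon)
      if (c0 > c1) next
      if (any(m[r0:r1, c0:c1])) n <- n + 1L
    }
  }
  n
}

# Random sparse-to-dense Bernoulli mask, guaranteed non-empty.
random_mask <- function(side, p = 0.2) {
  m <- matrix(runif(side^2) < p, side, side)
  if (!any(m)) m[sample.int(side^2, 1L)] <- TRUE
  lesion_mask(m)
}

# Otsu by exhaustive scan of all 255 split points.
brute_otsu <- function(px) {
  px <- as.integer(px)
  n <- length(px)
  best_t <- NA_integer_; best_v <- -Inf
  for (t in 0:254) {
    lo <- px[px <= t]; hi <- px[px > t]
    if (length(lo) == 0L || length(hi) == 0L) next
    v <- (length(lo) / n) * (length(hi) / n) * (mean(lo) - mean(hi))^2
    if (v > best_v + 1e-12) { best_v <- v; best_t <- t }
  }
  best_t
}

# Silhouette by direct per-point loops over the pairwise distances.
brute_silhouette <- function(x, cl) {
  n <- nrow(x)
  cl <- as.integer(factor(cl))
  d <- as.matrix(dist(x))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(cl == cl[i] & seq_len(n) != i)
    if (length(own) == 0L) { s[i] <- 0; next }
    a <- mean(d[i, own])
    b <- min(vapply(setdiff(unique(cl), cl[i]),
                    function(g) mean(d[i, cl == g]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# K-means inertia recomputed from scratch for given assignments.
brute_inertia <- function(x, cl) {
  total <- 0
  for (g in unique(cl)) {
    xi <- x[cl == g, , drop = FALSE]
    ctr <- colMeans(xi)
    total <- total + sum(sweep(xi, 2, ctr)^2)
  }
  total
}

# AUC as the fraction of concordant (pos, neg) pairs, ties counting half.
brute_auc <- function(fd_pos, fd_neg) {
  conc <- 0
  for (p in fd_pos) for (q in fd_neg) {
    conc <- conc + (p > q) + 0.5 * (p == q)
  }
  conc / (length(fd_pos) * length(fd_neg))
}

# Two-class cohort used across the classification tests.
mw_cohort <- function(n = 500, seed = 7) {
  make_cohort(
    tibble::tibble(label = c("non-metastatic melanoma", "nevus"),
                   n = n, median_fd = c(1.755, 1.651), sd_fd = 0.08),
    seed = seed)
}

# Bare pixel values of a mask/image, attributes stripped.
px <- function(m) matrix(c(unclass(m)), nrow(m), ncol(m))
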