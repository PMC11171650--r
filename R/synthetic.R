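# Synthetic inputs: fractal rasters of analytically known dimension (to
# validate the estimator) and diagnosis-labelled FD cohorts (to exercise the
# classification and clustering stages without an image archive).

#' Render a deterministic fractal (or Euclidean) test mask
#'
#' Generates binary rasters whose box-counting dimension is known in closed
#' form, so the estimator can be validated against analytic values:
#' Sierpinski carpet (log 8 / log 3), Sierpinski triangle (log 3 / log 2),
#' Koch curve (log 4 / log 3), filled square and disk (2), axis-aligned line
#' (1), plus a seeded `random_blob` with no analytic dimension.
#'
#' @param kind One of `"sierpinski_carpet"`, `"sierpinski_triangle"`,
#'   `"koch_curve"`, `"filled_square"`, `"filled_disk"`, `"line"`,
#'   `"random_blob"`.
#' @param level_or_side Recursion level for the self-similar kinds
#'   (carpet/triangle/Koch), side or length in pixels for the others.
#' @param seed RNG seed, used by `random_blob` only.
#' @return A [lesion_mask()] with attribute `theoretical_fd` (NA for
#'   `random_blob`).
#' @examples
#' m <- make_fractal_mask("sierpinski_carpet", 4)
#' foreground_count(m)  # 8^4 = 4096
#' @export
make_fractal_mask <- function(kind, level_or_side, seed = 1L) {
  k <- level_or_side
  mask <- switch(
    kind,
    sierpinski_carpet = {
      if (3^k > 2187) stop_value("carpet side exceeds the 2187 px limit.")
      m <- matrix(1L, 1L, 1L)
      cell <- matrix(c(1L, 1L, 1L, 1L, 0L, 1L, 1L, 1L, 1L), 3L, 3L)
      for (i in seq_len(k)) m <- kronecker(cell, m)
      structure(m > 0L, fd = log(8) / log(3))
    },
    sierpinski_triangle = {
      if (2^k > 2187) stop_value("triangle side exceeds the 2187 px limit.")
      side <- 2L^k
      ij <- expand.grid(i = 0:(side - 1L), j = 0:(side - 1L))
      m <- matrix(bitwAnd(ij$i, ij$j) == 0L, side, side)
      structure(m, fd = log(3) / log(2))
    },
    koch_curve = {
      structure(koch_raster(k), fd = log(4) / log(3))
    },
    filled_square = {
      if (k > 2187) stop_value("side exceeds the 2187 px limit.")
      structure(matrix(TRUE, k, k), fd = 2)
    },
    filled_disk = {
      if (k > 2187) stop_value("side exceeds the 2187 px limit.")
      ctr <- (k + 1) / 2
      rad <- k / 2 - 0.5
      ij <- expand.grid(r = seq_len(k), c = seq_len(k))
      m <- matrix((ij$r - ctr)^2 + (ij$c - ctr)^2 <= rad^2, k, k)
      structure(m, fd = 2)
    },
    line = {
      if (k > 2187) stop_value("length exceeds the 2187 px limit.")
      m <- matrix(FALSE, k, k)
      m[max(1L, k %/% 2L), ] <- TRUE
      structure(m, fd = 1)
    },
    random_blob = {
      structure(random_blob_mask(k, seed), fd = NA_real_)
    },
    stop_value(paste0("unknown fractal kind: ", kind)))
  out <- lesion_mask(matrix(as.logical(mask), nrow(mask), ncol(mask)),
                     source_id = paste0(kind, "_", k))
  attr(out, "theoretical_fd") <- attr(mask, "fd")
  out
}

# Koch curve at recursion `level` on a canvas 3^6 = 729 px wide, drawn as a
# 1-px polyline. The curve spans the full width; canvas height fits the
# classic bump (729 * sqrt(3)/6 ~ 211 px) with a margin.
koch_raster <- function(level = 5L) {
  if (level < 1L || level > 6L) stop_value("koch level must be in 1..6.")
  p <- matrix(c(0, 0, 729, 0), ncol = 2, byrow = TRUE)
  for (i in seq_len(level)) {
    new <- list()
    for (s in seq_len(nrow(p) - 1L)) {
      a <- p[s, ]; b <- p[s + 1L, ]
      d <- (b - a) / 3
      m1 <- a + d
      m2 <- a + 2 * d
      rot <- c(d[1] * cos(pi / 3) - d[2] * sin(pi / 3),
               d[1] * sin(pi / 3) + d[2] * cos(pi / 3))
      apex <- m1 + rot
      new[[s]] <- rbind(a, m1, apex, m2)
    }
    p <- rbind(do.call(rbind, new), p[nrow(p), ])
  }
  ht <- ceiling(729 * sqrt(3) / 6) + 8L
  m <- matrix(FALSE, ht, 729L)
  for (s in seq_len(nrow(p) - 1L)) {
    a <- p[s, ]; b <- p[s + 1L, ]
    len <- sqrt(sum((b - a)^2))
    t <- seq(0, 1, length.out = max(2L, ceiling(len * 4)))
    x <- pmin(pmax(round(a[1] + t * (b[1] - a[1]) + 0.5), 1L), 729L)
    y <- pmin(pmax(round(ht - 4L - (a[2] + t * (b[2] - a[2]))), 1L), ht)
    m[cbind(y, x)] <- TRUE
  }
  m
}

# Seeded irregular blob: union of overlapping disks with jittered radii
# around the canvas centre, then the largest component. Emulates a lesion
# silhouette with a rough margin; no analytic dimension.
random_blob_mask <- function(side, seed) {
  if (side < 16 || side > 2187) stop_value("blob side must be in 16..2187.")
  with_local_seed(seed, {
    ctr <- side / 2
    n_disks <- 24L
    ang <- runif(n_disks, 0, 2 * pi)
    rad <- runif(n_disks, 0, side / 6)
    cx <- ctr + rad * cos(ang)
    cy <- ctr + rad * sin(ang)
    rr <- runif(n_disks, side / 12, side / 5)
    ij <- expand.grid(r = seq_len(side), c = seq_len(side))
    m <- matrix(FALSE, side, side)
    for (d in seq_len(n_disks)) {
      m <- m | matrix((ij$r - cy[d])^2 + (ij$c - cx[d])^2 <= rr[d]^2,
                      side, side)
    }
    lab <- label_components(m)
    sizes <- tabulate(lab[lab > 0L])
    lab == which.max(sizes)
  })
}

# Evaluate `expr` under a temporary RNG state; the caller's stream resumes
# untouched afterwards.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Render a mask as a synthetic lesion photograph
#'
#' Produces the grayscale image a dermatoscope-style capture of the mask
#' would yield: dark lesion on a light field plus Gaussian pixel noise.
#' Binarizing the result recovers the input mask to within the noise.
#'
#' @param mask A [lesion_mask()].
#' @param fg_intensity Lesion (foreground) intensity, 0-255 (default 30).
#' @param bg_intensity Field (background) intensity, 0-255 (default 220).
#' @param noise_sd Gaussian noise standard deviation in intensity units; the
#'   intensities must differ by more than `4 * noise_sd` so recovery stays
#'   reliable.
#' @param seed RNG seed for the noise.
#' @return A [gray_image()] of the same dimensions as `mask`.
#' @export
render_lesion_photo <- function(mask, fg_intensity = 30, bg_intensity = 220,
                                noise_sd = 5, seed = 1L) {
  if (abs(fg_intensity - bg_intensity) <= 4 * noise_sd) {
    stop_value("|fg - bg| must exceed 4 * noise_sd for reliable recovery.")
  }
  base <- ifelse(unclass(mask), fg_intensity, bg_intensity)
  px <- with_local_seed(seed, base + rnorm(length(base), 0, noise_sd))
  px <- pmin(pmax(round(px), 0), 255)
  gray_image(matrix(px, nrow(mask), ncol(mask)),
             source_id = paste0(attr(mask, "source_id"), "_photo"))
}

#' Simulate a diagnosis-labelled fractal-dimension cohort
#'
#' Draws, for every row of `spec`, `n` FD values from a normal centred on
#' `median_fd` with standard deviation `sd_fd`, truncated to (1, 2) by
#' inverse-CDF sampling. Output is bitwise reproducible for a given seed.
#'
#' @param spec Data frame with columns `label` (diagnosis), `n` (count),
#'   `median_fd`, `sd_fd`; see [default_cohort_spec()].
#' @param seed Integer seed.
#' @return A tibble of lesion records: `id`, `diagnosis`, `fd`.
#' @examples
#' spec <- tibble::tibble(label = c("melanoma", "nevus"), n = c(50, 50),
#'                        median_fd = c(1.755, 1.651), sd_fd = 0.08)
#' cohort <- make_cohort(spec, seed = 7)
#' @export
make_cohort <- function(spec, seed = 1L) {
  spec <- as_tibble(spec)
  need <- c("label", "n", "median_fd", "sd_fd")
  if (!all(need %in% names(spec))) {
    stop_value("`spec` needs columns label, n, median_fd, sd_fd.")
  }
  if (any(spec$n < 0)) stop_value("class sizes must be non-negative.")
  if (any(spec$median_fd <= 0 | spec$median_fd >= 2)) {
    stop_value("median_fd must lie in (0, 2).")
  }
  if (any(spec$sd_fd <= 0)) stop_value("sd_fd must be positive.")
  with_local_seed(seed, {
    rows <- purrr::pmap(spec[need], function(label, n, median_fd, sd_fd) {
      if (n == 0) return(NULL)
      lo <- pnorm(1, median_fd, sd_fd)
      hi <- pnorm(2, median_fd, sd_fd)
      u <- runif(n, lo, hi)
      tibble(diagnosis = label, fd = stats::qnorm(u, median_fd, sd_fd))
    })
    out <- dplyr::bind_rows(rows)
    out$id <- sprintf("SYN-%06d", seq_len(nrow(out)))
    dplyr::select(out, "id", "diagnosis", "fd")
  })
}
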