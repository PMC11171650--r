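# Imaging stage: raster -> 512x512 8-bit grayscale -> binary lesion mask ->
# background-free single-component mask.

#' Construct a grayscale image object
#'
#' Wraps an integer matrix of 8-bit intensities (0-255) together with an
#' identifier for provenance tracking. Rows index image rows (top to bottom),
#' columns index image columns (left to right).
#'
#' @param pixels Integer matrix with values in 0-255.
#' @param source_id Character scalar identifying the image origin.
#' @return A `gray_image` object (an integer matrix with attributes).
#' @export
gray_image <- function(pixels, source_id = "unknown") {
  if (!is.matrix(pixels)) stop_value("`pixels` must be a matrix.")
  px <- as.integer(round(pixels))
  if (anyNA(px) || any(px < 0L) || any(px > 255L)) {
    stop_value("grayscale intensities must be integers in [0, 255].")
  }
  out <- matrix(px, nrow = nrow(pixels), ncol = ncol(pixels))
  structure(out, class = c("gray_image", "matrix", "array"),
            source_id = as.character(source_id))
}

#' Load a raster image as an 8-bit grayscale bitmap
#'
#' Reads a PNG/JPEG/TIFF raster, converts colour planes to grayscale by
#' luminance weighting (0.299 R + 0.587 G + 0.114 B), and resizes to a square
#' `target_side` x `target_side` bitmap with bilinear interpolation. Aspect
#' ratio is deliberately not preserved: every image enters the fractal
#' estimator on an identical pixel lattice.
#'
#' @param path Path to an image file.
#' @param target_side Side of the square output bitmap in pixels (default 512).
#' @return A [gray_image()] with `source_id` set to the file name.
#' @export
load_gray_image <- function(path, target_side = 512L) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    stop_ingest(paste0("cannot read image: ", path))
  }
  if (file.size(path) == 0L) {
    stop_ingest(paste0("zero-byte image file: ", path))
  }
  img <- tryCatch(EBImage::readImage(path), error = function(e) {
    stop_ingest(paste0("failed to decode '", path, "': ", conditionMessage(e)))
  })
  dat <- EBImage::imageData(img)
  if (length(dim(dat)) == 3L) {
    nch <- dim(dat)[3]
    w <- switch(as.character(min(nch, 3L)),
                "1" = 1, "2" = c(1, 0), "3" = c(0.299, 0.587, 0.114))
    gray <- matrix(0, dim(dat)[1], dim(dat)[2])
    for (ch in seq_along(w)) gray <- gray + w[ch] * dat[, , ch]
    dat <- gray
  }
  img <- EBImage::Image(dat, colormode = "Grayscale")
  if (any(dim(dat)[1:2] != target_side)) {
    img <- EBImage::resize(img, w = target_side, h = target_side)
  }
  px <- t(EBImage::imageData(img))  # EBImage stores x (width) first
  px <- pmin(pmax(round(px * 255), 0), 255)
  gray_image(px, source_id = basename(path))
}

#' Construct a binary lesion mask
#'
#' @param pixels Logical matrix, `TRUE` for lesion foreground.
#' @param threshold Intensity threshold that produced the mask, if any.
#' @param source_id Identifier inherited from the source image.
#' @return A `lesion_mask` object (a logical matrix with attributes).
#' @export
lesion_mask <- function(pixels, threshold = NA_real_, source_id = "unknown") {
  if (!is.matrix(pixels) || !is.logical(pixels)) {
    stop_value("`pixels` must be a logical matrix.")
  }
  structure(pixels, class = c("lesion_mask", "matrix", "array"),
            threshold = threshold, source_id = as.character(source_id))
}

#' @export
print.lesion_mask <- function(x, ...) {
  cat(sprintf("<lesion_mask> %d x %d, %d foreground px (threshold %s)\n",
              nrow(x), ncol(x), foreground_count(x),
              format(attr(x, "threshold"))))
  invisible(x)
}

#' Number of foreground pixels in a mask
#' @param mask A [lesion_mask()].
#' @return Integer count of foreground pixels.
#' @export
foreground_count <- function(mask) sum(mask)

#' Otsu threshold of an 8-bit image
#'
#' Picks the intensity `t` in 0-254 maximising the between-class variance of
#' the split into pixels `<= t` and `> t`. Ties resolve to the lowest
#' threshold.
#'
#' @param img A [gray_image()].
#' @return Integer threshold in 0-254.
#' @export
otsu_threshold <- function(img) {
  counts <- tabulate(as.integer(img) + 1L, nbins = 256L)
  n <- sum(counts)
  lev <- 0:255
  w0 <- cumsum(counts)                 # pixels <= t
  s0 <- cumsum(counts * lev)
  mu_t <- s0[256] / n
  valid <- w0 > 0 & w0 < n
  if (!any(valid)) {
    stop_degenerate_image("constant-intensity image: no separable classes.")
  }
  t_all <- lev[1:255]
  w0 <- w0[1:255]; s0 <- s0[1:255]
  mu0 <- s0 / w0
  mu1 <- (s0[length(s0)] * 0 + (mu_t * n - s0)) / (n - w0)
  bcv <- (w0 / n) * (1 - w0 / n) * (mu0 - mu1)^2
  bcv[!valid[1:255]] <- -Inf
  t_all[which.max(bcv)]
}

#' Binarize a grayscale image into a lesion mask
#'
#' The lesion is assumed darker than the surrounding skin, so foreground is
#' the `<= threshold` class; set `invert = TRUE` for light-on-dark inputs.
#'
#' @param img A [gray_image()].
#' @param method `"otsu"` (default) for Otsu's between-class-variance
#'   threshold, or `"fixed"` to use `fixed_threshold`.
#' @param fixed_threshold Intensity in 0-255, required when `method = "fixed"`.
#' @param invert If `TRUE`, foreground is the brighter class.
#' @return A [lesion_mask()] carrying the threshold used.
#' @export
binarize <- function(img, method = c("otsu", "fixed"), fixed_threshold = NULL,
                     invert = FALSE) {
  method <- match.arg(method)
  if (method == "otsu") {
    thr <- otsu_threshold(img)
  } else {
    if (is.null(fixed_threshold) || fixed_threshold < 0 || fixed_threshold > 255) {
      stop_value("`fixed_threshold` must be supplied in [0, 255].")
    }
    if (min(img) == max(img)) {
      stop_degenerate_image("constant-intensity image: no separable classes.")
    }
    thr <- fixed_threshold
  }
  fg <- if (invert) unclass(img) > thr else unclass(img) <= thr
  lesion_mask(matrix(fg, nrow(img), ncol(img)), threshold = thr,
              source_id = attr(img, "source_id"))
}

# 8-connected component labels of a logical matrix; 0 = background.
# igraph does the component search; edges link each foreground pixel to its
# E, S, SE and SW foreground neighbours.
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask)
  lab <- integer(nr * nc)
  if (length(idx) == 0L) return(matrix(lab, nr, nc))
  pos <- match(seq_len(nr * nc), idx)  # pixel -> vertex id
  r <- ((idx - 1L) %% nr) + 1L
  c <- ((idx - 1L) %/% nr) + 1L
  edge_to <- function(dr, dc) {
    ok <- r + dr >= 1L & r + dr <= nr & c + dc >= 1L & c + dc <= nc
    nb <- (c[ok] + dc - 1L) * nr + (r[ok] + dr)
    keep <- mask[nb]
    cbind(pos[idx[ok][keep]], pos[nb[keep]])
  }
  edges <- rbind(edge_to(0L, 1L), edge_to(1L, 0L), edge_to(1L, 1L),
                 edge_to(-1L, 1L))
  g <- igraph::graph_from_edgelist(
    matrix(edges, ncol = 2), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  lab[idx] <- comp[seq_along(idx)]
  matrix(lab, nr, nc)
}

#' Eliminate the image background from a binary mask
#'
#' Retains only the largest 8-connected foreground component, which removes
#' speckle from hair, bubbles and other acquisition artifacts; interior holes
#' are filled by default so that area-style box counting is stable. When two
#' components tie on area, the one whose first foreground pixel occurs
#' earliest in row-major order (top row first, left to right) is kept.
#'
#' @param mask A [lesion_mask()] with at least one foreground pixel.
#' @param min_component_px Components smaller than this are ignored outright.
#' @param fill_holes Fill interior holes of the retained component.
#' @return A [lesion_mask()] whose foreground is a single connected component.
#' @export
remove_background <- function(mask, min_component_px = 1L, fill_holes = TRUE) {
  if (foreground_count(mask) == 0L) {
    stop_empty_mask("mask has no foreground pixels.")
  }
  lab <- label_components(mask)
  sizes <- tabulate(lab[lab > 0L])
  sizes[sizes < min_component_px] <- 0L
  if (all(sizes == 0L)) {
    stop_empty_mask("no component reaches `min_component_px`.")
  }
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    # row-major scan: row varies slowest, column fastest
    rowmajor <- t(lab)
    first <- vapply(best, function(b) which(rowmajor == b)[1], numeric(1))
    best <- best[which.min(first)]
  }
  keep <- lab == best
  if (fill_holes) {
    keep <- EBImage::imageData(EBImage::fillHull(EBImage::Image(keep * 1))) > 0
  }
  lesion_mask(matrix(keep, nrow(mask), ncol(mask)),
              threshold = attr(mask, "threshold"),
              source_id = attr(mask, "source_id"))
}

#' Write a mask as a 1-bit-style PNG for audit
#'
#' @param mask A [lesion_mask()].
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  EBImage::writeImage(EBImage::Image(t(unclass(mask) * 1)), path)
  invisible(path)
}

#' Write a grayscale image to disk
#'
#' @param img A [gray_image()].
#' @param path Output path; format chosen from the extension (png/jpeg/tiff).
#' @param quality JPEG quality (ignored for other formats).
#' @return `path`, invisibly.
#' @export
write_gray_image <- function(img, path, quality = 100) {
  EBImage::writeImage(EBImage::Image(t(unclass(img) / 255)), path,
                      quality = quality)
  invisible(path)
}
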