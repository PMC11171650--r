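# Box-counting fractal dimension: N(eps) across a schedule of box sides,
# then the least-squares slope of log N(eps) against log(1/eps).

#' Count covering boxes at one scale
#'
#' Overlays a grid of `epsilon` x `epsilon` cells (anchored at `grid_offset`,
#' in pixels) on the mask and counts the cells containing at least one
#' foreground pixel. Partial cells at the edges count as cells.
#'
#' @param mask A [lesion_mask()] with at least one foreground pixel.
#' @param epsilon Box side in pixels, between 1 and the mask side.
#' @param grid_offset Length-2 integer vector (row, col) shifting the grid
#'   anchor; default `c(0, 0)` anchors at the mask origin.
#' @return Integer number of occupied boxes.
#' @export
count_boxes <- function(mask, epsilon, grid_offset = c(0L, 0L)) {
  side <- max(nrow(mask), ncol(mask))
  if (length(epsilon) != 1L || is.na(epsilon) || epsilon < 1 || epsilon > side) {
    stop_value(sprintf("`epsilon` must lie in [1, %d].", side))
  }
  idx <- which(unclass(mask))
  if (length(idx) == 0L) stop_empty_mask("mask has no foreground pixels.")
  nr <- nrow(mask)
  r0 <- ((idx - 1L) %% nr)            # 0-based row
  c0 <- ((idx - 1L) %/% nr)           # 0-based col
  kr <- floor((r0 - grid_offset[1]) / epsilon)
  kc <- floor((c0 - grid_offset[2]) / epsilon)
  ncell <- ceiling(side / epsilon) + 2L  # enough to disambiguate shifted grids
  length(unique(kr * (2L * ncell) + kc))
}

#' Build a schedule of box sizes
#'
#' @param mask_side Mask side in pixels (at least 2).
#' @param scheme `"dyadic"` for powers of two up to `mask_side / 2`,
#'   `"ternary"` for powers of three up to `mask_side / 3`, or `"custom"`.
#' @param custom Strictly increasing box sides in pixels, used when
#'   `scheme = "custom"`.
#' @return Increasing integer vector of box sides.
#' @examples
#' box_schedule(512)            # 2 4 8 ... 256
#' box_schedule(243, "ternary") # 3 9 27 81
#' @export
box_schedule <- function(mask_side, scheme = c("dyadic", "ternary", "custom"),
                         custom = NULL) {
  scheme <- match.arg(scheme)
  if (mask_side < 2) stop_value("`mask_side` must be at least 2.")
  if (scheme == "dyadic") {
    as.integer(2^seq_len(floor(log2(mask_side / 2))))
  } else if (scheme == "ternary") {
    as.integer(3^seq_len(floor(log(mask_side / 3) / log(3) + 1e-9)))
  } else {
    if (is.null(custom) || length(custom) == 0L) {
      stop_value("`custom` schedule is empty.")
    }
    if (any(diff(custom) <= 0)) {
      stop_value("`custom` schedule must be strictly increasing.")
    }
    if (any(custom < 1) || any(custom > mask_side)) {
      stop_value("`custom` schedule must lie within [1, mask_side].")
    }
    as.integer(custom)
  }
}

#' Estimate the box-counting fractal dimension of a mask
#'
#' Computes N(eps) for every box side in `schedule` and fits
#' log N(eps) ~ log(1/eps) by ordinary least squares; the slope is the
#' box-counting dimension D_b. A degenerate series with all counts equal
#' yields D_b = 0 rather than an error.
#'
#' @param mask A [lesion_mask()].
#' @param schedule Increasing vector of box sides, e.g. from
#'   [box_schedule()]; at least two scales.
#' @param grid_offset Grid anchor passed to [count_boxes()].
#' @param margin_only If `TRUE`, count boxes over the mask's boundary pixels
#'   (its morphological gradient) instead of the full foreground.
#' @return An `fd_estimate` object: fields `db`, `intercept`, `r_squared`,
#'   and the `(epsilon, n_boxes)` series. Use [tidy()] for the series and
#'   [glance()] for the fit summary.
#' @export
estimate_fd <- function(mask, schedule, grid_offset = c(0L, 0L),
                        margin_only = FALSE) {
  if (length(schedule) < 2L) {
    stop_value("`schedule` needs at least two scales to define a slope.")
  }
  if (any(diff(schedule) <= 0)) {
    stop_value("`schedule` must be strictly increasing.")
  }
  if (margin_only) mask <- mask_boundary(mask)
  n_boxes <- vapply(schedule, function(e) count_boxes(mask, e, grid_offset),
                    numeric(1))
  x <- log(1 / schedule)
  y <- log(n_boxes)
  if (var(y) == 0) {
    db <- 0; intercept <- y[1]; r2 <- 1
  } else {
    fit <- lm(y ~ x)
    db <- unname(coef(fit)[2])
    intercept <- unname(coef(fit)[1])
    # collinear log-log points trip summary.lm's perfect-fit warning
    r2 <- suppressWarnings(summary(fit)$r.squared)
  }
  structure(
    list(db = db, intercept = intercept, r_squared = r2,
         series = tibble(epsilon = as.numeric(schedule), n_boxes = n_boxes),
         mask_side = max(nrow(mask), ncol(mask)),
         foreground_count = foreground_count(mask),
         threshold = attr(mask, "threshold"),
         source_id = attr(mask, "source_id"),
         margin_only = margin_only),
    class = "fd_estimate")
}

#' @export
print.fd_estimate <- function(x, ...) {
  cat(sprintf("<fd_estimate> D_b = %.4f (R^2 = %.4f, %d scales, %s)\n",
              x$db, x$r_squared, nrow(x$series), x$source_id))
  invisible(x)
}

# Boundary pixels: foreground with at least one 4-neighbour outside the mask
# (image border counts as outside).
mask_boundary <- function(mask) {
  m <- unclass(mask)
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- m
  interior <- pad[1:nr, 2:(nc + 1L)] & pad[3:(nr + 2L), 2:(nc + 1L)] &
    pad[2:(nr + 1L), 1:nc] & pad[2:(nr + 1L), 3:(nc + 2L)]
  lesion_mask(m & !interior, threshold = attr(mask, "threshold"),
              source_id = attr(mask, "source_id"))
}

#' Run the full image-to-dimension pipeline on one file
#'
#' Composes [load_gray_image()], [binarize()], [remove_background()] and
#' [estimate_fd()] and records the parameters used.
#'
#' @param path Path to a raster image.
#' @param target_side Square bitmap side for ingestion (default 512).
#' @param method,fixed_threshold,invert Passed to [binarize()].
#' @param fill_holes Passed to [remove_background()].
#' @param scheme,custom Passed to [box_schedule()].
#' @param margin_only Passed to [estimate_fd()].
#' @return An `fd_estimate` (see [estimate_fd()]).
#' @export
estimate_fd_image <- function(path, target_side = 512L,
                              method = "otsu", fixed_threshold = NULL,
                              invert = FALSE, fill_holes = TRUE,
                              scheme = "dyadic", custom = NULL,
                              margin_only = FALSE) {
  id <- basename(path)
  withCallingHandlers(
    {
      img <- load_gray_image(path, target_side = target_side)
      mask <- binarize(img, method = method, fixed_threshold = fixed_threshold,
                       invert = invert)
      mask <- remove_background(mask, fill_holes = fill_holes)
      sched <- box_schedule(target_side, scheme = scheme, custom = custom)
      estimate_fd(mask, sched, margin_only = margin_only)
    },
    lesionfd_error = function(e) {
      e$message <- paste0("[", id, "] ", conditionMessage(e))
      stop(e)
    })
}

#' Batch fractal-dimension analysis over an image directory
#'
#' Runs [estimate_fd_image()] over every image, joining diagnoses from a
#' label table (`image_id,diagnosis`; CSV, or XLSX when the readxl package is
#' installed). One row per image is returned in the schema the downstream
#' classification and clustering stages consume.
#'
#' @param paths Character vector of image paths, or a directory containing
#'   them.
#' @param labels `NULL`, a data frame with columns `image_id` and `diagnosis`,
#'   or a path to a CSV/XLSX file with those columns.
#' @param ... Passed to [estimate_fd_image()].
#' @return A tibble with columns `image_id`, `diagnosis`, `fd`, `r_squared`,
#'   `n_scales`, `threshold_used`.
#' @export
estimate_fd_batch <- function(paths, labels = NULL, ...) {
  if (length(paths) == 1L && dir.exists(paths)) {
    paths <- list.files(paths, pattern = "\\.(png|jpe?g|tiff?)$",
                        ignore.case = TRUE, full.names = TRUE)
  }
  if (length(paths) == 0L) stop_ingest("no images to analyse.")
  lab <- read_label_table(labels)
  rows <- purrr::map(paths, function(p) {
    est <- estimate_fd_image(p, ...)
    tibble(image_id = est$source_id, fd = est$db, r_squared = est$r_squared,
           n_scales = nrow(est$series), threshold_used = est$threshold)
  })
  out <- dplyr::bind_rows(rows)
  if (!is.null(lab)) {
    out <- dplyr::left_join(out, lab, by = "image_id")
  } else {
    out$diagnosis <- NA_character_
  }
  dplyr::select(out, "image_id", "diagnosis", "fd", "r_squared", "n_scales",
                "threshold_used")
}

read_label_table <- function(labels) {
  if (is.null(labels)) return(NULL)
  if (is.data.frame(labels)) {
    lab <- as_tibble(labels)
  } else if (is.character(labels) && length(labels) == 1L) {
    if (!file.exists(labels)) {
      stop_ingest(paste0("label table not found: ", labels))
    }
    lab <- if (grepl("\\.xlsx?$", labels, ignore.case = TRUE)) {
      if (!requireNamespace("readxl", quietly = TRUE)) {
        stop_ingest("reading XLSX label tables requires the readxl package.")
      }
      as_tibble(readxl::read_excel(labels))
    } else {
      readr::read_csv(labels, show_col_types = FALSE)
    }
  } else {
    stop_value("`labels` must be NULL, a data frame, or a file path.")
  }
  if (!all(c("image_id", "diagnosis") %in% names(lab))) {
    stop_value("label table must have columns `image_id` and `diagnosis`.")
  }
  lab[c("image_id", "diagnosis")]
}
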