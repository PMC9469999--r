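#' Ordered short-axis image stack
#'
#' Bundles an ordered list of 2D intensity slices with their in-plane pixel
#' spacing and through-plane slice spacing (thickness + gap). Slices are
#' ordered base to apex.
#'
#' @param slices A single matrix or a list of numeric matrices sharing one
#'   grid shape.
#' @param pixel_spacing Length-2 numeric, mm per pixel as `c(row, col)`, or a
#'   single number used for both.
#' @param slice_spacing Positive mm between slice centers (thickness + gap).
#' @return An object of class `lge_image_stack`: a list with elements
#'   `slices`, `pixel_spacing`, `slice_spacing`.
#' @export
#' @examples
#' st <- image_stack(matrix(0, 8, 8), pixel_spacing = c(1.5, 1.5))
#' n_slices(st)
image_stack <- function(slices, pixel_spacing = c(1, 1), slice_spacing = 8) {
  if (is.matrix(slices)) slices <- list(slices)
  stopifnot(is.list(slices), length(slices) >= 1)
  if (length(pixel_spacing) == 1) pixel_spacing <- rep(pixel_spacing, 2)
  dims <- vapply(slices, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all slices must share one grid shape", call. = FALSE)
  if (any(pixel_spacing <= 0) || slice_spacing <= 0)
    stop("spacings must be positive", call. = FALSE)
  structure(list(slices = slices,
                 pixel_spacing = as.numeric(pixel_spacing),
                 slice_spacing = as.numeric(slice_spacing)),
            class = "lge_image_stack")
}

#' @rdname image_stack
#' @param x An `lge_image_stack`.
#' @export
n_slices <- function(x) length(x$slices)

#' @export
print.lge_image_stack <- function(x, ...) {
  d <- dim(x$slices[[1]])
  cat(sprintf("<lge_image_stack> %d slice(s) of %dx%d px, %.3gx%.3g mm px, %.3g mm slice spacing\n",
              n_slices(x), d[1], d[2], x$pixel_spacing[1], x$pixel_spacing[2],
              x$slice_spacing))
  invisible(x)
}

#' Closed planar contour
#'
#' A closed, simple (non-self-intersecting) polyline of ordered vertices in
#' pixel coordinates `(row, col)`. The closing edge from the last vertex back
#' to the first is implicit. Orientation is recorded as counterclockwise on
#' the displayed image (row 1 at the top).
#'
#' @param vertices Numeric matrix with columns `(row, col)`, at least 8 rows.
#' @return An object of class `lge_contour`: the vertex matrix with an
#'   attribute `ccw` (logical).
#' @export
contour <- function(vertices) {
  vertices <- as.matrix(vertices)
  if (!is.numeric(vertices) || ncol(vertices) != 2)
    stop("vertices must be an n x 2 numeric matrix (row, col)", call. = FALSE)
  # drop an explicit duplicated closing vertex
  n <- nrow(vertices)
  if (n > 1 && all(vertices[1, ] == vertices[n, ]))
    vertices <- vertices[-n, , drop = FALSE]
  if (nrow(vertices) < 8)
    stop("a contour needs at least 8 vertices", call. = FALSE)
  colnames(vertices) <- c("row", "col")
  # signed area in display coordinates (x = col, y = -row); positive <=> ccw
  x <- vertices[, "col"]; y <- -vertices[, "row"]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  a <- sum(x * y2 - x2 * y) / 2
  structure(vertices, class = "lge_contour", ccw = a > 0)
}

#' @rdname contour
#' @param x An `lge_contour`.
#' @export
contour_perimeter <- function(x) {
  v <- unclass(x)
  d <- v - v[c(2:nrow(v), 1), , drop = FALSE]
  sum(sqrt(rowSums(d^2)))
}

#' Left-ventricle segmentation of one slice
#'
#' Epicardial and endocardial closed contours plus the LV/RV junction
#' landmark and the millimetre offsets applied when building the myocardial
#' mask (the band is eroded by `epi_offset_mm` from the epicardial side and
#' by `endo_offset_mm` from the endocardial side).
#'
#' @param epi,endo `lge_contour` objects; `endo` must lie strictly inside
#'   `epi`.
#' @param rv_insertion Optional `(row, col)` landmark at the anterior RV
#'   insertion (LV/RV junction).
#' @param endo_offset_mm,epi_offset_mm Nonnegative offsets in mm.
#' @return An object of class `lge_lv_seg`.
#' @export
lv_segmentation <- function(epi, endo, rv_insertion = NULL,
                            endo_offset_mm = 0, epi_offset_mm = 0) {
  stopifnot(inherits(epi, "lge_contour"), inherits(endo, "lge_contour"))
  if (endo_offset_mm < 0 || epi_offset_mm < 0)
    stop("offsets must be nonnegative", call. = FALSE)
  ce <- colMeans(unclass(epi))
  if (!all(point_in_polygon(unclass(endo), unclass(epi))))
    stop("endocardial contour must lie strictly inside the epicardial contour",
         call. = FALSE)
  structure(list(epi = epi, endo = endo, rv_insertion = rv_insertion,
                 endo_offset_mm = endo_offset_mm, epi_offset_mm = epi_offset_mm,
                 center = ce),
            class = "lge_lv_seg")
}

#' Even-odd point-in-polygon test
#'
#' Crossing-number (even-odd rule) test of points against a closed polygon.
#' Used by the rasterizer: a pixel belongs to a region when its center is
#' inside the polygon.
#'
#' @param points n x 2 matrix of `(row, col)` points.
#' @param polygon m x 2 matrix of polygon vertices (closing edge implicit).
#' @return Logical vector of length n.
#' @keywords internal
point_in_polygon <- function(points, polygon) {
  points <- as.matrix(points); polygon <- as.matrix(polygon)
  px <- points[, 2]; py <- points[, 1]
  vx <- polygon[, 2]; vy <- polygon[, 1]
  n <- length(vx)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Rasterize a contour to a binary mask
#'
#' @param contour An `lge_contour` (or n x 2 vertex matrix).
#' @param shape Length-2 integer `c(nrow, ncol)` of the target grid.
#' @return Logical matrix: `TRUE` where the pixel center is inside the
#'   polygon under the even-odd rule.
#' @export
rasterize_contour <- function(contour, shape) {
  v <- as.matrix(unclass(contour))
  rr <- seq_len(shape[1]); cc <- seq_len(shape[2])
  # restrict the test to the bounding box for speed
  r0 <- max(1L, floor(min(v[, 1]))); r1 <- min(shape[1], ceiling(max(v[, 1])))
  c0 <- max(1L, floor(min(v[, 2]))); c1 <- min(shape[2], ceiling(max(v[, 2])))
  out <- matrix(FALSE, shape[1], shape[2])
  if (r0 > r1 || c0 > c1) return(out)
  grid <- cbind(rep(r0:r1, times = c1 - c0 + 1),
                rep(c0:c1, each = r1 - r0 + 1))
  out[grid[point_in_polygon(grid, v), , drop = FALSE]] <- TRUE
  out
}

#' Region statistics
#'
#' Pixel count, min, max, mean, standard deviation and physical area of the
#' pixels selected by a binary mask. The SD is the population SD (divide by
#' `n`), fixed so that n-SD thresholds are exactly reproducible.
#'
#' @param image Numeric matrix of intensities.
#' @param mask Logical/0-1 matrix of the same shape; must select at least one
#'   pixel.
#' @param pixel_spacing Length-2 mm-per-pixel `c(row, col)` (or one number).
#' @return A one-row tibble with columns `n_pixels`, `min`, `max`, `mean`,
#'   `sd`, `area_mm2`.
#' @export
#' @examples
#' img <- matrix(1:4, 2, 2)
#' region_stats(img, matrix(TRUE, 2, 2))
region_stats <- function(image, mask, pixel_spacing = c(1, 1)) {
  if (!all(dim(image) == dim(mask)))
    stop("mask and image shapes differ", call. = FALSE)
  if (length(pixel_spacing) == 1) pixel_spacing <- rep(pixel_spacing, 2)
  v <- image[as.logical(mask)]
  if (length(v) == 0) stop("empty region: mask selects no pixels", call. = FALSE)
  n <- length(v)
  m <- mean(v)
  tibble::tibble(
    n_pixels = n,
    min = min(v), max = max(v), mean = m,
    sd = sqrt(sum((v - m)^2) / n),
    area_mm2 = n * pixel_spacing[1] * pixel_spacing[2]
  )
}

#' Intensity histogram of a masked region
#'
#' Bins the masked intensities into `n_bins` equal-width bins spanning
#' exactly `[min, max]` of the region. Counts always sum to the mask size;
#' the value `max` falls in the last bin. A degenerate region (single
#' distinct value) puts every pixel in one bin.
#'
#' @inheritParams region_stats
#' @param n_bins Number of bins, at least 2.
#' @param highlight Optional length-2 numeric intensity interval recorded for
#'   display (e.g. the interval matching a lesion segmentation).
#' @return An object of class `lge_histogram`: list with `breaks` (length
#'   `n_bins + 1`), `counts` (length `n_bins`) and `highlight`.
#' @export
region_histogram <- function(image, mask, n_bins = 32, highlight = NULL) {
  if (n_bins < 2) stop("n_bins must be at least 2", call. = FALSE)
  v <- image[as.logical(mask)]
  if (length(v) == 0) stop("empty region: mask selects no pixels", call. = FALSE)
  lo <- min(v); hi <- max(v)
  if (hi == lo) {
    breaks <- lo + seq(0, 1, length.out = n_bins + 1)
    counts <- c(length(v), rep(0L, n_bins - 1))
  } else {
    breaks <- seq(lo, hi, length.out = n_bins + 1)
    idx <- pmin(floor((v - lo) / (hi - lo) * n_bins) + 1L, n_bins)
    counts <- tabulate(idx, nbins = n_bins)
  }
  structure(list(breaks = breaks, counts = as.integer(counts),
                 highlight = highlight),
            class = "lge_histogram")
}

#' @export
print.lge_histogram <- function(x, ...) {
  cat(sprintf("<lge_histogram> %d bins over [%.4g, %.4g], %d pixels\n",
              length(x$counts), min(x$breaks), max(x$breaks), sum(x$counts)))
  invisible(x)
}

#' Per-pixel tissue label map
#'
#' Integer grid of tissue classes within the myocardium (see [lge_labels()])
#' together with the provenance of the segmentation that produced it.
#'
#' @param labels Integer matrix with values in `lge_labels()`.
#' @param method Character tag of the producing method.
#' @param params Named list of the parameters used.
#' @return An object of class `lge_label_map`.
#' @export
label_map <- function(labels, method = "manual", params = list()) {
  labels <- matrix(as.integer(labels), nrow(labels), ncol(labels))
  if (!all(labels %in% c(LABEL_OUTSIDE, LABEL_REMOTE, LABEL_LESION, LABEL_MVO)))
    stop("labels must be in 0:3 (outside/remote/lesion/mvo)", call. = FALSE)
  structure(list(labels = labels, method = method, params = params),
            class = "lge_label_map")
}

#' @export
print.lge_label_map <- function(x, ...) {
  tab <- table(factor(x$labels, levels = 0:3,
                      labels = names(lge_labels())))
  cat(sprintf("<lge_label_map> method '%s': %s\n", x$method,
              paste(names(tab), as.integer(tab), sep = "=", collapse = " ")))
  invisible(x)
}

#' @rdname label_map
#' @param x An `lge_label_map`.
#' @param class One of `"remote"`, `"lesion"`, `"mvo"`, `"myocardium"`,
#'   `"infarct"` (lesion + mvo).
#' @return `class_mask()`: logical matrix.
#' @export
class_mask <- function(x, class) {
  l <- x$labels
  switch(class,
         remote = l == LABEL_REMOTE,
         lesion = l == LABEL_LESION,
         mvo = l == LABEL_MVO,
         infarct = l == LABEL_LESION | l == LABEL_MVO,
         myocardium = l != LABEL_OUTSIDE,
         stop("unknown class: ", class, call. = FALSE))
}
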