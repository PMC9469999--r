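# Internal grid utilities: shifts, connected components, morphology, angles.

# Shift a matrix by (dr, dc), padding with `fill`.
shift_mat <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  r_lo <- max(1, 1 + dr); r_hi <- min(nr, nr + dr)
  c_lo <- max(1, 1 + dc); c_hi <- min(nc, nc + dc)
  if (r_lo <= r_hi && c_lo <= c_hi)
    out[r_lo:r_hi, c_lo:c_hi] <- m[(r_lo:r_hi) - dr, (c_lo:c_hi) - dc]
  out
}

neighbor_offsets <- function(connectivity = 8) {
  o4 <- rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  if (connectivity == 4) return(o4)
  rbind(o4, c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
}

# Connected-component labeling by iterative min-label propagation.
# EBImage::bwlabel is 4-connectivity only; the segmentation methods need 8.
conn_comp <- function(mask, connectivity = 8) {
  d <- dim(mask)
  mask <- as.logical(mask); dim(mask) <- d
  if (!any(mask)) return(matrix(0L, d[1], d[2]))
  # work on the bounding box only
  ri <- range(which(rowSums(mask) > 0)); ci <- range(which(colSums(mask) > 0))
  if (ri[1] > 1 || ri[2] < d[1] || ci[1] > 1 || ci[2] < d[2]) {
    sub <- conn_comp(mask[ri[1]:ri[2], ci[1]:ci[2], drop = FALSE], connectivity)
    out <- matrix(0L, d[1], d[2])
    out[ri[1]:ri[2], ci[1]:ci[2]] <- sub
    return(out)
  }
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0, nr, nc)
  lab[mask] <- which(mask)  # seed with linear index
  offs <- neighbor_offsets(connectivity)
  repeat {
    new <- lab
    for (k in seq_len(nrow(offs))) {
      sh <- shift_mat(lab, offs[k, 1], offs[k, 2], fill = 0)
      upd <- mask & sh > 0 & (new == 0 | sh < new)
      new[upd] <- sh[upd]
    }
    if (identical(new, lab)) break
    lab <- new
  }
  # renumber 1..k
  ids <- sort(unique(lab[lab > 0]))
  out <- matrix(0L, nr, nc)
  out[mask] <- match(lab[mask], ids)
  out
}

disc_brush <- function(radius_px) {
  k <- as.integer(radius_px)
  if (k <= 0) return(NULL)
  EBImage::makeBrush(2L * k + 1L, shape = "disc")
}

erode_disc <- function(mask, radius_px) {
  b <- disc_brush(radius_px)
  if (is.null(b)) return(mask)
  EBImage::erode(mask * 1, b) > 0.5
}

dilate_disc <- function(mask, radius_px) {
  b <- disc_brush(radius_px)
  if (is.null(b)) return(mask)
  EBImage::dilate(mask * 1, b) > 0.5
}

fill_holes <- function(mask) {
  EBImage::fillHull(mask * 1) > 0.5
}

# 8-neighbor dilation by one pixel (cheap, exact for adjacency tests).
dilate1 <- function(mask) {
  out <- as.logical(mask); dim(out) <- dim(mask)
  for (k in seq_len(8)) {
    o <- neighbor_offsets(8)[k, ]
    out <- out | shift_mat(mask, o[1], o[2], fill = FALSE)
  }
  out
}

# Angle of each pixel center about `center`, counterclockwise on the
# displayed image (row 1 at top), in [0, 2*pi).
pixel_angles <- function(shape, center) {
  rr <- matrix(seq_len(shape[1]), shape[1], shape[2])
  cc <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  a <- atan2(-(rr - center[1]), cc - center[2])
  (a + 2 * pi) %% (2 * pi)
}

pixel_radii <- function(shape, center) {
  rr <- matrix(seq_len(shape[1]), shape[1], shape[2])
  cc <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  sqrt((rr - center[1])^2 + (cc - center[2])^2)
}

point_angle <- function(p, center) {
  (atan2(-(p[1] - center[1]), p[2] - center[2]) + 2 * pi) %% (2 * pi)
}

# TRUE when angle theta lies on the counterclockwise arc from a to b.
angle_in_arc <- function(theta, a, b) {
  span <- (b - a) %% (2 * pi)
  ((theta - a) %% (2 * pi)) <= span
}

# Bilinear interpolation of image at fractional (row, col) points.
bilinear <- function(image, rows, cols) {
  nr <- nrow(image); nc <- ncol(image)
  rows <- pmin(pmax(as.numeric(rows), 1), nr)
  cols <- pmin(pmax(as.numeric(cols), 1), nc)
  r0 <- pmin(floor(rows), nr - 1); c0 <- pmin(floor(cols), nc - 1)
  fr <- rows - r0; fc <- cols - c0
  i00 <- image[cbind(r0, c0)];     i10 <- image[cbind(r0 + 1, c0)]
  i01 <- image[cbind(r0, c0 + 1)]; i11 <- image[cbind(r0 + 1, c0 + 1)]
  i00 * (1 - fr) * (1 - fc) + i10 * fr * (1 - fc) +
    i01 * (1 - fr) * fc + i11 * fr * fc
}
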