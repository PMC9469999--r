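# Endocardial surface length/area, transmural extent, wiper clipping.

#' Wiper pair
#'
#' Two angles about the LV center marking the lateral edges of the infarct.
#' The covered interval runs counterclockwise from `from` to `to` on the
#' displayed image.
#'
#' @param from,to Angles in radians (distinct modulo 2*pi).
#' @param propagate Whether the pair propagates across slices.
#' @return A list of class `lge_wiper_pair`.
#' @export
wiper_pair <- function(from, to, propagate = TRUE) {
  if (((to - from) %% (2 * pi)) == 0 && to != from + 2 * pi)
    stop("wiper angles must be distinct modulo 2*pi", call. = FALSE)
  structure(list(from = from %% (2 * pi),
                 to = if ((to - from) %% (2 * pi) == 0) from %% (2 * pi) + 2 * pi
                      else to %% (2 * pi),
                 full = (to - from) %% (2 * pi) == 0,
                 propagate = propagate),
            class = "lge_wiper_pair")
}

# densify a closed contour: sub-sample every edge so arc computations are
# accurate on coarse polygons.
densify_contour <- function(ct, per_edge = 16) {
  v <- as.matrix(unclass(ct))
  n <- nrow(v)
  nxt <- v[c(2:n, 1), , drop = FALSE]
  t <- seq(0, 1, length.out = per_edge + 1)[-(per_edge + 1)]
  pts <- do.call(rbind, lapply(seq_len(n), function(i)
    cbind(v[i, 1] + t * (nxt[i, 1] - v[i, 1]),
          v[i, 2] + t * (nxt[i, 2] - v[i, 2]))))
  pts
}

# wiper pair from the lesion pixels adjacent to the endocardial border:
# the interval is the complement of the largest angular gap between them.
wipers_from_mask <- function(lesion_mask, endo_inside, lv_center) {
  adj <- lesion_mask & dilate1(endo_inside)
  if (!any(adj)) return(NULL)
  th <- sort(pixel_angles(dim(lesion_mask), lv_center)[adj])
  if (length(th) == 1) return(wiper_pair(th - 0.01, th + 0.01))
  gaps <- c(diff(th), th[1] + 2 * pi - th[length(th)])
  i <- which.max(gaps)
  if (i == length(th)) wiper_pair(th[1], th[length(th)])
  else wiper_pair(th[i + 1], th[i])
}

#' Endocardial surface length (ESL)
#'
#' Percent of the endocardial contour perimeter subtended by the infarct:
#' the arc length of the contour inside the wiper interval (or, in mask
#' mode, inside the angular extent of lesion pixels adjacent to the
#' endocardial border) divided by the total perimeter, times 100.
#'
#' @param endo An `lge_contour` (closed endocardial contour).
#' @param wipers An [wiper_pair()], or `NULL` to derive the edges from
#'   `lesion_mask`.
#' @param lesion_mask Optional logical lesion mask (mask mode).
#' @param lv_center `(row, col)` center; defaults to the contour centroid.
#' @param pixel_spacing mm per pixel (isotropic assumed for arc lengths when
#'   a single number; anisotropic spacing scales coordinates per axis).
#' @return One-row tibble with `esl_percent`, `arc_mm`, `perimeter_mm`.
#' @export
esl <- function(endo, wipers = NULL, lesion_mask = NULL, lv_center = NULL,
                pixel_spacing = c(1, 1)) {
  if (length(pixel_spacing) == 1) pixel_spacing <- rep(pixel_spacing, 2)
  if (is.null(lv_center)) lv_center <- colMeans(unclass(endo))
  if (is.null(wipers)) {
    if (is.null(lesion_mask) || !any(lesion_mask))
      return(tibble::tibble(esl_percent = 0, arc_mm = 0,
                            perimeter_mm = perim_mm(endo, pixel_spacing)))
    endo_in <- rasterize_contour(endo, dim(lesion_mask))
    wipers <- wipers_from_mask(lesion_mask != 0, endo_in, lv_center)
    if (is.null(wipers))
      return(tibble::tibble(esl_percent = 0, arc_mm = 0,
                            perimeter_mm = perim_mm(endo, pixel_spacing)))
  }
  pts <- densify_contour(endo)
  mm <- cbind(pts[, 1] * pixel_spacing[1], pts[, 2] * pixel_spacing[2])
  nxt <- mm[c(2:nrow(mm), 1), , drop = FALSE]
  seglen <- sqrt(rowSums((nxt - mm)^2))
  mid <- (pts + pts[c(2:nrow(pts), 1), , drop = FALSE]) / 2
  th <- (atan2(-(mid[, 1] - lv_center[1]), mid[, 2] - lv_center[2]) + 2 * pi) %% (2 * pi)
  inside <- if (isTRUE(wipers$full)) rep(TRUE, length(th))
            else angle_in_arc(th, wipers$from, wipers$to)
  per <- sum(seglen); arc <- sum(seglen[inside])
  tibble::tibble(esl_percent = 100 * arc / per, arc_mm = arc,
                 perimeter_mm = per)
}

perim_mm <- function(ct, pixel_spacing) {
  pts <- densify_contour(ct)
  mm <- cbind(pts[, 1] * pixel_spacing[1], pts[, 2] * pixel_spacing[2])
  nxt <- mm[c(2:nrow(mm), 1), , drop = FALSE]
  sum(sqrt(rowSums((nxt - mm)^2)))
}

#' Endocardial surface area (ESA)
#'
#' Multi-slice analogue of ESL: the absolute ESA is the sum over slices of
#' (ESL/100 x perimeter) x slice spacing, and the percent ESA is the
#' perimeter-weighted mean of the slice ESLs (total infarct arc over total
#' perimeter, x100).
#'
#' @param esl_percent Numeric vector of per-slice ESL values (%).
#' @param perimeter_mm Per-slice endocardial perimeters (mm).
#' @param slice_spacing mm between slice centers (thickness + gap).
#' @return One-row tibble with `esa_mm2` and `esa_percent`.
#' @export
#' @examples
#' esa(rep(25, 4), rep(2 * pi * 20, 4), slice_spacing = 8)
esa <- function(esl_percent, perimeter_mm, slice_spacing) {
  stopifnot(length(esl_percent) == length(perimeter_mm),
            length(esl_percent) >= 1)
  arcs <- esl_percent / 100 * perimeter_mm
  tibble::tibble(esa_mm2 = sum(arcs) * slice_spacing,
                 esa_percent = 100 * sum(arcs) / sum(perimeter_mm))
}

#' Transmural extent per angular sector
#'
#' For each of `n_sectors` angular sectors about the LV center, casts radial
#' rays from the endocardial to the epicardial border and reports the
#' fraction of wall thickness occupied by lesion: lesion ray samples over
#' myocardial ray samples. A sector whose rays never hit the myocardium is
#' reported missing (`NA`).
#'
#' @param myo_mask,lesion_mask Logical masks.
#' @param lv_center `(row, col)` LV center.
#' @param n_sectors Number of sectors (>= 4).
#' @param rays_per_sector Rays cast per sector.
#' @param dr Radial sampling step (pixels).
#' @return Tibble with `sector`, `theta_mid` and `fraction`, carrying the
#'   attribute `mean_transmurality`: the mean fraction over sectors that
#'   contain lesion.
#' @export
transmurality <- function(myo_mask, lesion_mask, lv_center, n_sectors = 24,
                          rays_per_sector = 7, dr = 0.25) {
  stopifnot(n_sectors >= 4)
  d <- dim(myo_mask)
  myo_mask <- as.logical(myo_mask); dim(myo_mask) <- d
  lesion_mask <- as.logical(lesion_mask); dim(lesion_mask) <- d
  shape <- dim(myo_mask)
  rmax <- sqrt(sum(shape^2))
  radii <- seq(dr, rmax, by = dr)
  edges <- seq(0, 2 * pi, length.out = n_sectors + 1)
  frac <- rep(NA_real_, n_sectors)
  ray_fracs <- numeric()
  for (s in seq_len(n_sectors)) {
    th <- edges[s] + (seq_len(rays_per_sector) - 0.5) / rays_per_sector *
      (edges[s + 1] - edges[s])
    n_myo_tot <- 0; n_les_tot <- 0
    for (a in th) {
      rows <- round(lv_center[1] - radii * sin(a))
      cols <- round(lv_center[2] + radii * cos(a))
      ok <- rows >= 1 & rows <= shape[1] & cols >= 1 & cols <= shape[2]
      ii <- cbind(rows[ok], cols[ok])
      n_myo <- sum(myo_mask[ii]); n_les <- sum(lesion_mask[ii])
      n_myo_tot <- n_myo_tot + n_myo; n_les_tot <- n_les_tot + n_les
      if (n_myo > 0 && n_les > 0) ray_fracs <- c(ray_fracs, n_les / n_myo)
    }
    if (n_myo_tot > 0) frac[s] <- n_les_tot / n_myo_tot
  }
  out <- tibble::tibble(sector = seq_len(n_sectors),
                        theta_mid = (edges[-1] + edges[-(n_sectors + 1)]) / 2,
                        fraction = frac)
  # summary over rays (not sectors): immune to wedge/sector misalignment
  attr(out, "mean_transmurality") <-
    if (length(ray_fracs)) mean(ray_fracs) else 0
  out
}

#' Clip a segmentation to the wiper interval
#'
#' Reclassifies lesion and MVO pixels outside the wiper interval as remote;
#' pixels inside the interval are untouched. Used to clean up segmentation
#' results a posteriori.
#'
#' @param labelmap An `lge_label_map`.
#' @param wipers An [wiper_pair()].
#' @param lv_center `(row, col)` LV center.
#' @return The clipped `lge_label_map`.
#' @export
clip_to_wipers <- function(labelmap, wipers, lv_center) {
  if (isTRUE(wipers$full)) return(labelmap)
  th <- pixel_angles(dim(labelmap$labels), lv_center)
  outside <- !angle_in_arc(th, wipers$from, wipers$to)
  sel <- outside & (labelmap$labels == LABEL_LESION |
                      labelmap$labels == LABEL_MVO)
  labelmap$labels[sel] <- LABEL_REMOTE
  labelmap
}
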