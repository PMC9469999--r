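# AHA 17-segment model: slice levels, angular segment assignment from the
# LV/RV junction landmark, per-segment statistics.

#' The AHA 17-segment model
#'
#' Segment ids 1-17 with their level (basal 1-6, mid 7-12, apical 13-16,
#' apex 17) and angular span (60 degrees basal/mid, 90 apical, 360 apex).
#'
#' @return A 17-row tibble with columns `id`, `level`, `name`, `span_deg`.
#' @export
#' @examples
#' nrow(aha_model())  # 17
aha_model <- function() {
  nm6 <- c("anterior", "anteroseptal", "inferoseptal",
           "inferior", "inferolateral", "anterolateral")
  nm4 <- c("anterior", "septal", "inferior", "lateral")
  tibble::tibble(
    id = 1:17,
    level = c(rep("basal", 6), rep("mid", 6), rep("apical", 4), "apex"),
    name = c(paste("basal", nm6), paste("mid", nm6),
             paste("apical", nm4), "apex"),
    span_deg = c(rep(60, 12), rep(90, 4), 360)
  )
}

#' Classify slices into basal / mid / apical levels
#'
#' Splits the ordered (base-to-apex) segmented slices into three contiguous
#' groups of near-equal size; a remainder is distributed base-first, so 8
#' slices give 3/3/2.
#'
#' @param n_or_stack An [image_stack()] or a slice count.
#' @param indices Optional indices of the segmented slices (default: all).
#' @return Tibble with columns `slice` and `level`.
#' @export
classify_slice_levels <- function(n_or_stack, indices = NULL) {
  n <- if (inherits(n_or_stack, "lge_image_stack")) n_slices(n_or_stack)
       else as.integer(n_or_stack)
  if (is.null(indices)) indices <- seq_len(n)
  indices <- sort(as.integer(indices))
  k <- length(indices)
  if (k < 3) stop("need at least 3 segmented slices", call. = FALSE)
  base_size <- k %/% 3
  sizes <- rep(base_size, 3) + (seq_len(3) <= k %% 3)
  tibble::tibble(slice = indices,
                 level = rep(c("basal", "mid", "apical"), times = sizes))
}

#' Assign AHA segments to myocardial pixels
#'
#' Measures each pixel's angle about the LV center; the ray towards the
#' anterior RV-insertion landmark is the boundary between the anterior and
#' anteroseptal segments, and ids increase counterclockwise on the displayed
#' image. Basal and mid levels use six 60-degree sectors, the apical level
#' four 90-degree sectors; an `"apex"` level assigns segment 17 everywhere.
#'
#' @param myo_mask Logical myocardium mask.
#' @param lv_center `(row, col)` LV center.
#' @param rv_insertion `(row, col)` anterior RV-insertion landmark (distinct
#'   from the center).
#' @param level `"basal"`, `"mid"`, `"apical"` or `"apex"`.
#' @return An object of class `lge_segment_assignment`: list with `ids`
#'   (integer grid, 0 outside the myocardium) and `reference_angle`.
#' @export
assign_segments <- function(myo_mask, lv_center, rv_insertion,
                            level = c("basal", "mid", "apical", "apex")) {
  level <- match.arg(level)
  if (all(rv_insertion == lv_center))
    stop("degenerate landmark: RV insertion equals the LV center", call. = FALSE)
  d <- dim(myo_mask)
  myo_mask <- as.logical(myo_mask); dim(myo_mask) <- d
  ref <- point_angle(rv_insertion, lv_center)
  th <- pixel_angles(dim(myo_mask), lv_center)
  off <- (th - ref) %% (2 * pi)
  ids <- matrix(0L, nrow(myo_mask), ncol(myo_mask))
  if (level == "apex") {
    ids[myo_mask] <- 17L
  } else if (level == "apical") {
    ids[myo_mask] <- 13L + pmin(floor(off[myo_mask] / (pi / 2)), 3)
  } else {
    base_id <- if (level == "basal") 1L else 7L
    ids[myo_mask] <- base_id + pmin(floor(off[myo_mask] / (pi / 3)), 5)
  }
  structure(list(ids = ids, reference_angle = ref, level = level),
            class = "lge_segment_assignment")
}

#' Per-segment, per-class statistics table
#'
#' One row of [region_stats()] per (segment, tissue class) present on the
#' slice, plus per-slice totals per class (`segment = 0`). Pixel counts are
#' exactly additive: each total equals the sum of its segment rows.
#'
#' @param image Intensity matrix.
#' @param labelmap An `lge_label_map`.
#' @param assignment An `lge_segment_assignment` for the same slice.
#' @param pixel_spacing mm per pixel.
#' @param slice Slice index recorded in the table.
#' @return Tibble with columns `slice`, `segment`, `class`, `n_pixels`,
#'   `min`, `max`, `mean`, `sd`, `area_mm2`. Empty cells are omitted
#'   (equivalently `n = 0`).
#' @export
segment_stats_table <- function(image, labelmap, assignment,
                                pixel_spacing = c(1, 1), slice = 1L) {
  classes <- c(remote = LABEL_REMOTE, lesion = LABEL_LESION, mvo = LABEL_MVO)
  segs <- sort(unique(assignment$ids[assignment$ids > 0]))
  rows <- list()
  for (cl in names(classes)) {
    cmask <- labelmap$labels == classes[[cl]]
    for (sg in c(segs, 0L)) {
      m <- cmask & (if (sg == 0L) assignment$ids > 0 else assignment$ids == sg)
      if (!any(m)) next
      rows[[length(rows) + 1]] <- dplyr::bind_cols(
        tibble::tibble(slice = as.integer(slice), segment = as.integer(sg),
                       class = cl),
        region_stats(image, m, pixel_spacing))
    }
  }
  if (!length(rows))
    return(tibble::tibble(slice = integer(), segment = integer(),
                          class = character(), n_pixels = integer(),
                          min = numeric(), max = numeric(), mean = numeric(),
                          sd = numeric(), area_mm2 = numeric()))
  dplyr::arrange(dplyr::bind_rows(rows), .data$class, .data$segment)
}

#' Whole-stack AHA report
#'
#' Classifies slice levels, assigns segments on every slice and stacks the
#' per-segment statistics, appending whole-myocardium totals per class
#' (`slice = 0`, `segment = 0`).
#'
#' @param stack An [image_stack()].
#' @param labelmaps List of `lge_label_map`, one per slice.
#' @param lv_centers List (or single) `(row, col)` centers per slice.
#' @param rv_insertion `(row, col)` landmark (shared across slices).
#' @return Tibble as in [segment_stats_table()].
#' @export
aha_report <- function(stack, labelmaps, lv_centers, rv_insertion) {
  n <- n_slices(stack)
  if (!is.list(lv_centers)) lv_centers <- rep(list(lv_centers), n)
  # fewer than 3 slices cannot be split into levels; report them as mid
  levels <- if (n >= 3) classify_slice_levels(n)
            else tibble::tibble(slice = seq_len(n), level = "mid")
  tabs <- lapply(seq_len(n), function(i) {
    myo <- labelmaps[[i]]$labels != LABEL_OUTSIDE
    asg <- assign_segments(myo, lv_centers[[i]], rv_insertion,
                           levels$level[levels$slice == i])
    segment_stats_table(stack$slices[[i]], labelmaps[[i]], asg,
                        stack$pixel_spacing, slice = i)
  })
  tab <- dplyr::bind_rows(tabs)
  # whole-myocardium totals per class
  totals <- list()
  for (cl in c("remote", "lesion", "mvo")) {
    masks <- lapply(seq_len(n), function(i)
      labelmaps[[i]]$labels == lge_labels()[[cl]])
    nn <- sum(vapply(masks, sum, numeric(1)))
    if (nn == 0) next
    v <- unlist(lapply(seq_len(n), function(i) stack$slices[[i]][masks[[i]]]))
    totals[[cl]] <- tibble::tibble(
      slice = 0L, segment = 0L, class = cl, n_pixels = length(v),
      min = min(v), max = max(v), mean = mean(v),
      sd = sqrt(sum((v - mean(v))^2) / length(v)),
      area_mm2 = length(v) * prod(stack$pixel_spacing))
  }
  dplyr::bind_rows(tab, dplyr::bind_rows(totals))
}

#' Bullseye values for the 17-segment model
#'
#' Collapses a statistics table to one value per AHA segment id (1-17),
#' suitable for JSON export or a polar-map display. Segments with no pixels
#' get `NA` (segment 17 receives pixels only when an apex-cap slice was
#' flagged).
#'
#' @param table A [segment_stats_table()]/[aha_report()] tibble.
#' @param class Tissue class to extract.
#' @param value Column to extract.
#' @return Named numeric vector of length 17 (names `"1"`..`"17"`).
#' @export
bullseye_values <- function(table, class = "lesion", value = "area_mm2") {
  seg_rows <- table[table$segment > 0 & table$class == class, ]
  agg <- tapply(seg_rows[[value]], seg_rows$segment, sum)
  out <- setNames(rep(NA_real_, 17), as.character(1:17))
  out[names(agg)] <- as.numeric(agg)
  out
}
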