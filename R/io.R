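# Readers/writers: DICOM series, NIfTI label maps and masks, CSV statistics,
# JSON contours and bullseye values.
#
# The DICOM layer is a minimal explicit-VR little-endian single-frame
# reader/writer (uncompressed, MONOCHROME2, 16-bit): enough to round-trip
# short-axis series with pixel spacing, slice geometry and rescale
# slope/intercept. Writers are deterministic: the same inputs produce
# byte-identical files.

TRANSFER_SYNTAX_LE <- "1.2.840.10008.1.2.1"
UID_ROOT <- "1.2.826.0.1.3680043.8.498"

dcm_element <- function(group, element, vr, value) {
  u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
  u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")
  if (vr %in% c("UI", "CS", "DS", "IS", "LO", "SH")) {
    body <- charToRaw(as.character(value))
    if (length(body) %% 2 == 1)  # UI pads with nul, text VRs with space
      body <- c(body, if (vr == "UI") as.raw(0) else charToRaw(" "))
  } else if (vr == "US") {
    body <- u16(value)
  } else if (vr == "UL") {
    body <- u32(value)
  } else if (vr == "OW") {
    body <- value  # already raw
  } else stop("unsupported VR ", vr)
  hdr <- c(u16(group), u16(element), charToRaw(vr))
  if (vr %in% c("OB", "OW", "SQ", "UN", "UT")) {
    c(hdr, as.raw(c(0, 0)), u32(length(body)), body)
  } else {
    c(hdr, u16(length(body)), body)
  }
}

write_dicom_file <- function(path, pixels_raw16, rows, cols, pixel_spacing,
                             slice_thickness, slice_spacing, slice_location,
                             instance_number, series_uid, sop_uid,
                             slope = 1, intercept = 0) {
  ds <- function(x) format(x, digits = 15, trim = TRUE, scientific = FALSE)
  meta <- c(
    dcm_element(0x0002, 0x0002, "UI", paste0(UID_ROOT, ".1")),
    dcm_element(0x0002, 0x0003, "UI", sop_uid),
    dcm_element(0x0002, 0x0010, "UI", TRANSFER_SYNTAX_LE))
  meta <- c(dcm_element(0x0002, 0x0000, "UL", length(meta)), meta)
  body <- c(
    dcm_element(0x0008, 0x0018, "UI", sop_uid),
    dcm_element(0x0008, 0x0060, "CS", "MR"),
    dcm_element(0x0018, 0x0050, "DS", ds(slice_thickness)),
    dcm_element(0x0018, 0x0088, "DS", ds(slice_spacing)),
    dcm_element(0x0020, 0x000E, "UI", series_uid),
    dcm_element(0x0020, 0x0013, "IS", as.character(instance_number)),
    dcm_element(0x0020, 0x1041, "DS", ds(slice_location)),
    dcm_element(0x0028, 0x0002, "US", 1),
    dcm_element(0x0028, 0x0004, "CS", "MONOCHROME2"),
    dcm_element(0x0028, 0x0010, "US", rows),
    dcm_element(0x0028, 0x0011, "US", cols),
    dcm_element(0x0028, 0x0030, "DS",
                paste(ds(pixel_spacing[1]), ds(pixel_spacing[2]), sep = "\\")),
    dcm_element(0x0028, 0x0100, "US", 16),
    dcm_element(0x0028, 0x0101, "US", 16),
    dcm_element(0x0028, 0x0102, "US", 15),
    dcm_element(0x0028, 0x0103, "US", 0),
    dcm_element(0x0028, 0x1052, "DS", ds(intercept)),
    dcm_element(0x0028, 0x1053, "DS", ds(slope)),
    dcm_element(0x7FE0, 0x0010, "OW", pixels_raw16))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, body), con)
  invisible(path)
}

read_dicom_file <- function(path) {
  bytes <- readBin(path, "raw", file.size(path))
  if (length(bytes) < 140 || rawToChar(bytes[129:132]) != "DICM")
    stop("not a DICOM file: ", path, call. = FALSE)
  pos <- 133
  u16 <- function(p) sum(as.integer(bytes[p:(p + 1)]) * c(1, 256))
  u32 <- function(p) sum(as.integer(bytes[p:(p + 3)]) * c(1, 256, 65536, 16777216))
  tags <- list()
  while (pos + 7 <= length(bytes)) {
    group <- u16(pos); element <- u16(pos + 2)
    vr <- rawToChar(bytes[(pos + 4):(pos + 5)])
    if (vr %in% c("OB", "OW", "SQ", "UN", "UT")) {
      len <- u32(pos + 8); vstart <- pos + 12
    } else {
      len <- u16(pos + 6); vstart <- pos + 8
    }
    key <- sprintf("%04X,%04X", group, element)
    val_bytes <- if (len > 0) bytes[vstart:(vstart + len - 1)] else raw(0)
    tags[[key]] <- list(vr = vr, bytes = val_bytes)
    pos <- vstart + len
  }
  getstr <- function(key) {
    t <- tags[[key]]
    if (is.null(t)) return(NULL)
    trimws(rawToChar(t$bytes[t$bytes != as.raw(0)]))
  }
  getnum <- function(key) {
    s <- getstr(key); if (is.null(s) || s == "") NULL else as.numeric(strsplit(s, "\\\\")[[1]])
  }
  getu16 <- function(key) {
    t <- tags[[key]]
    if (is.null(t)) NULL else readBin(t$bytes, "integer", size = 2,
                                      signed = FALSE, endian = "little")
  }
  rows <- getu16("0028,0010"); cols <- getu16("0028,0011")
  px <- tags[["7FE0,0010"]]
  if (is.null(rows) || is.null(cols) || is.null(px))
    stop("missing image data in ", path, call. = FALSE)
  vals <- readBin(px$bytes, "integer", n = rows * cols, size = 2,
                  signed = FALSE, endian = "little")
  list(
    pixels = matrix(vals, nrow = rows, byrow = TRUE),
    rows = rows, cols = cols,
    pixel_spacing = getnum("0028,0030"),
    slice_thickness = getnum("0018,0050"),
    slice_spacing = getnum("0018,0088"),
    slice_location = getnum("0020,1041"),
    instance_number = getnum("0020,0013"),
    series_uid = getstr("0020,000E"),
    sop_uid = getstr("0008,0018"),
    intercept = getnum("0028,1052"),
    slope = getnum("0028,1053"))
}

#' Write an image stack as a single-frame DICOM series
#'
#' Stores each slice as an explicit-VR little-endian MR image with pixel
#' spacing, slice geometry, slice location (base to apex) and the given
#' rescale slope/intercept: stored values are `round((I - intercept) /
#' slope)` and must fit in 16 bits unsigned.
#'
#' @param stack An [image_stack()].
#' @param dir Output directory (created if needed).
#' @param slope,intercept Rescale mapping `intensity = slope * stored +
#'   intercept`.
#' @param series_uid Series instance UID (deterministic default).
#' @return Invisibly, the written file paths.
#' @export
write_dicom_series <- function(stack, dir, slope = 1, intercept = 0,
                               series_uid = paste0(UID_ROOT, ".7.1")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(n_slices(stack))
  for (i in seq_len(n_slices(stack))) {
    raw_vals <- round((stack$slices[[i]] - intercept) / slope)
    if (any(raw_vals < 0) || any(raw_vals > 65535))
      stop("stored values out of 16-bit range; adjust slope/intercept",
           call. = FALSE)
    pr <- writeBin(as.integer(t(raw_vals)), raw(), size = 2, endian = "little")
    paths[i] <- file.path(dir, sprintf("slice_%03d.dcm", i))
    write_dicom_file(paths[i], pr, nrow(raw_vals), ncol(raw_vals),
                     stack$pixel_spacing,
                     slice_thickness = stack$slice_spacing,
                     slice_spacing = stack$slice_spacing,
                     slice_location = (i - 1) * stack$slice_spacing,
                     instance_number = i,
                     series_uid = series_uid,
                     sop_uid = paste0(series_uid, ".", i),
                     slope = slope, intercept = intercept)
  }
  invisible(paths)
}

#' Read a single-frame DICOM series
#'
#' Reads every DICOM file in a directory, checks they belong to one series,
#' sorts slices base to apex by slice location, applies the rescale
#' slope/intercept to the stored values, and returns the stack plus the
#' series metadata.
#'
#' @param dir Directory containing the `.dcm` files of one series.
#' @return A list with `stack` ([image_stack()]) and `metadata` (tibble:
#'   one row per slice with locations, instance numbers, UIDs, rescale).
#' @export
read_dicom_series <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.dcm$", full.names = TRUE))
  if (!length(files)) stop("no DICOM files in ", dir, call. = FALSE)
  parsed <- lapply(files, read_dicom_file)
  uids <- vapply(parsed, function(p) p$series_uid %||% "", "")
  if (length(unique(uids)) > 1)
    stop("mixed series; offending instances: ",
         paste(basename(files[uids != uids[1]]), collapse = ", "),
         call. = FALSE)
  locs <- vapply(parsed, function(p) (p$slice_location %||% NA_real_)[1], 0)
  if (any(is.na(locs))) stop("missing slice locations", call. = FALSE)
  ord <- order(locs)
  parsed <- parsed[ord]; files <- files[ord]; locs <- locs[ord]
  sp <- parsed[[1]]$pixel_spacing
  if (is.null(sp) || any(!is.finite(sp)) || any(sp <= 0))
    stop("missing pixel spacing", call. = FALSE)
  dz <- parsed[[1]]$slice_spacing %||% parsed[[1]]$slice_thickness
  if (is.null(dz)) {
    if (length(locs) > 1) dz <- diff(locs)[1]
    else stop("missing slice spacing", call. = FALSE)
  }
  slices <- lapply(parsed, function(p) {
    sl <- (p$slope %||% 1)[1]; ic <- (p$intercept %||% 0)[1]
    sl * p$pixels + ic
  })
  meta <- tibble::tibble(
    file = basename(files), slice_location = locs,
    instance_number = vapply(parsed, function(p) (p$instance_number %||% NA_real_)[1], 0),
    series_uid = uids[ord][1],
    sop_uid = vapply(parsed, function(p) p$sop_uid %||% "", ""),
    slope = vapply(parsed, function(p) (p$slope %||% 1)[1], 0),
    intercept = vapply(parsed, function(p) (p$intercept %||% 0)[1], 0))
  list(stack = image_stack(slices, sp, dz), metadata = meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- NIfTI -------------------------------------------------------------------

#' Write / read a label map as NIfTI
#'
#' Class codes follow [lge_labels()] (0 outside, 1 remote, 2 lesion, 3 mvo).
#' Method provenance goes to a JSON sidecar `<path>.json`.
#'
#' @param labelmap An `lge_label_map` (or list of them for a multi-slice
#'   volume).
#' @param path Output `.nii.gz` path.
#' @param pixel_spacing,slice_spacing Geometry stored in the NIfTI header.
#' @return `write_label_map()`: the path, invisibly. `read_label_map()`: an
#'   `lge_label_map` (first slice) or list of them.
#' @export
write_label_map <- function(labelmap, path, pixel_spacing = c(1, 1),
                            slice_spacing = 8) {
  lms <- if (inherits(labelmap, "lge_label_map")) list(labelmap) else labelmap
  arr <- array(0L, c(dim(lms[[1]]$labels), length(lms)))
  for (i in seq_along(lms)) arr[, , i] <- lms[[i]]$labels
  im <- RNifti::asNifti(arr)
  im <- RNifti::`pixdim<-`(im, c(pixel_spacing, slice_spacing))
  RNifti::writeNifti(im, path)
  sidecar <- paste0(path, ".json")
  jsonlite::write_json(list(method = lms[[1]]$method,
                            params = lms[[1]]$params,
                            labels = as.list(lge_labels())),
                       sidecar, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_label_map
#' @export
read_label_map <- function(path) {
  arr <- RNifti::readNifti(path)
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else
    list(method = "unknown", params = list())
  arr <- as.array(arr)
  if (length(dim(arr)) == 2) dim(arr) <- c(dim(arr), 1)
  lms <- lapply(seq_len(dim(arr)[3]), function(i)
    label_map(arr[, , i], meta$method, meta$params))
  if (length(lms) == 1) lms[[1]] else lms
}

# --- JSON contours and bullseye ----------------------------------------------

#' Write / read contours as JSON
#'
#' Serializes per-slice epicardial/endocardial vertex lists, offsets and the
#' RV-insertion landmark.
#'
#' @param segs A single `lge_lv_seg` or a list of them (one per slice).
#' @param path Output `.json` path.
#' @return `write_contours_json()`: the path, invisibly;
#'   `read_contours_json()`: a list of `lge_lv_seg`.
#' @export
write_contours_json <- function(segs, path) {
  if (inherits(segs, "lge_lv_seg")) segs <- list(segs)
  payload <- lapply(segs, function(s) list(
    epi = unname(apply(unclass(s$epi), 1, as.numeric, simplify = FALSE)),
    endo = unname(apply(unclass(s$endo), 1, as.numeric, simplify = FALSE)),
    rv_insertion = if (is.null(s$rv_insertion)) NULL else as.numeric(s$rv_insertion),
    endo_offset_mm = s$endo_offset_mm, epi_offset_mm = s$epi_offset_mm))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_contours_json
#' @export
read_contours_json <- function(path) {
  payload <- jsonlite::read_json(path)
  lapply(payload, function(s) {
    mk <- function(v) contour(do.call(rbind, lapply(v, unlist)))
    lv_segmentation(mk(s$epi), mk(s$endo),
                    rv_insertion = if (is.null(s$rv_insertion)) NULL
                                   else unlist(s$rv_insertion),
                    endo_offset_mm = s$endo_offset_mm %||% 0,
                    epi_offset_mm = s$epi_offset_mm %||% 0)
  })
}

#' Write bullseye values as JSON
#'
#' One entry per AHA segment id, `"1"` through `"17"`.
#'
#' @param values Named numeric vector from [bullseye_values()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_bullseye_json <- function(values, path) {
  stopifnot(length(values) == 17)
  jsonlite::write_json(as.list(values), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Export analysis results to a directory
#'
#' Writes the statistics table as CSV (stable column order, one row per
#' region x segment x slice plus totals), label maps as NIfTI with JSON
#' sidecars, and contours as JSON. Every file is re-readable by the package.
#'
#' @param dir Output directory.
#' @param stats_table Tibble from [segment_stats_table()] / [aha_report()].
#' @param labelmaps `lge_label_map` or list thereof.
#' @param contours `lge_lv_seg` or list thereof.
#' @param bullseye Named 17-vector from [bullseye_values()].
#' @param pixel_spacing,slice_spacing Geometry for NIfTI headers.
#' @return Invisibly, the named list of written paths.
#' @export
export_results <- function(dir, stats_table = NULL, labelmaps = NULL,
                           contours = NULL, bullseye = NULL,
                           pixel_spacing = c(1, 1), slice_spacing = 8) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  if (!is.null(stats_table)) {
    out$stats <- file.path(dir, "statistics.csv")
    write.csv(stats_table, out$stats, row.names = FALSE)
  }
  if (!is.null(labelmaps)) {
    out$labels <- file.path(dir, "labelmap.nii.gz")
    write_label_map(labelmaps, out$labels, pixel_spacing, slice_spacing)
  }
  if (!is.null(contours)) {
    out$contours <- file.path(dir, "contours.json")
    write_contours_json(contours, out$contours)
  }
  if (!is.null(bullseye)) {
    out$bullseye <- file.path(dir, "bullseye.json")
    write_bullseye_json(bullseye, out$bullseye)
  }
  invisible(out)
}
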