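# Synthetic LGE phantom: ring myocardium, wedge infarct with controllable
# size / transmural extent / %SE, optional MVO core, seeded noise at a
# target CNR, full ground truth.

#' Synthetic phantom specification
#'
#' Describes a short-axis LGE phantom: a ring myocardium around a bright
#' blood cavity on a dark background, with a subendocardial wedge lesion of
#' chosen angular extent whose transmural fraction varies sinusoidally about
#' a user-defined mean, optional hypointense MVO core inside the lesion,
#' percent signal enhancement (%SE) of the lesion over remote myocardium,
#' and seeded noise calibrated to a target contrast-to-noise ratio
#' (CNR = (lesion - remote) / noise SD).
#'
#' @param shape Grid shape `c(nrow, ncol)` in pixels.
#' @param pixel_spacing mm per pixel.
#' @param center LV center `(row, col)`; default is the grid center.
#' @param endo_radius_mm,epi_radius_mm Endocardial/epicardial radii (mm),
#'   `0 < endo < epi`.
#' @param lesion_center_deg,lesion_extent_deg Angular position and extent of
#'   the lesion wedge (degrees, counterclockwise convention).
#' @param transmural_mean,transmural_amplitude Mean transmural fraction in
#'   (0, 1] and the amplitude of its sinusoidal variation across the wedge.
#' @param pse Percent signal enhancement of lesion over remote myocardium
#'   (> 0). The default 300 reflects inversion-recovery LGE, where the
#'   nulled remote myocardium makes the infarct several-fold brighter (and
#'   FWHM thresholding requires %SE > 100 to be meaningful).
#' @param mvo `NULL`, or `list(extent_deg =, radial_span = c(lo, hi))` with
#'   the span given as fractions of the wall thickness from the endocardial
#'   border; must fit inside the lesion.
#' @param remote_intensity,background_intensity Base intensities; the lesion
#'   intensity is `remote * (1 + pse/100)`.
#' @param blood_intensity Cavity intensity; default 1.1 x lesion, exercising
#'   the bright-cavity/bright-lesion boundary.
#' @param mvo_intensity Intensity of the no-reflow core (default
#'   0.4 x remote).
#' @param noise `"gaussian"` (additive) or `"rician"` (magnitude of signal
#'   plus complex Gaussian noise, the physical model of magnitude MR).
#' @param target_cnr Target CNR; noise SD is set to
#'   `(lesion - remote) / target_cnr`. Alternatively give `noise_sd`
#'   directly; with neither the phantom is noiseless.
#' @param noise_sd Explicit noise SD (overridden by `target_cnr`).
#' @param seed Integer seed; the phantom is bit-reproducible from it.
#' @param n_slices Number of identical-geometry slices.
#' @param slice_spacing mm between slice centers.
#' @return A list of class `lge_phantom_spec`.
#' @export
phantom_spec <- function(shape = c(128, 128), pixel_spacing = c(1, 1),
                         center = NULL,
                         endo_radius_mm = 20, epi_radius_mm = 30,
                         lesion_center_deg = 0, lesion_extent_deg = 90,
                         transmural_mean = 1, transmural_amplitude = 0,
                         pse = 300, mvo = NULL,
                         remote_intensity = 100, background_intensity = 20,
                         blood_intensity = NULL, mvo_intensity = NULL,
                         noise = c("gaussian", "rician"),
                         target_cnr = NULL, noise_sd = NULL,
                         seed = 1L, n_slices = 1L, slice_spacing = 8) {
  noise <- match.arg(noise)
  if (length(pixel_spacing) == 1) pixel_spacing <- rep(pixel_spacing, 2)
  if (is.null(center)) center <- (shape + 1) / 2
  if (endo_radius_mm <= 0 || endo_radius_mm >= epi_radius_mm)
    stop("need 0 < endo radius < epi radius", call. = FALSE)
  if (transmural_mean <= 0 || transmural_mean > 1)
    stop("transmural fraction must be in (0, 1]", call. = FALSE)
  if (transmural_mean + transmural_amplitude > 1 + 1e-9 ||
      transmural_mean - transmural_amplitude <= 0)
    stop("transmural variation leaves (0, 1]", call. = FALSE)
  if (pse <= 0) stop("%SE must be positive", call. = FALSE)
  if (!is.null(target_cnr) && target_cnr <= 0)
    stop("target CNR must be positive", call. = FALSE)
  lesion_intensity <- remote_intensity * (1 + pse / 100)
  if (is.null(blood_intensity)) blood_intensity <- 1.1 * lesion_intensity
  if (is.null(mvo_intensity)) mvo_intensity <- 0.4 * remote_intensity
  if (!is.null(mvo)) {
    stopifnot(is.list(mvo), !is.null(mvo$extent_deg), !is.null(mvo$radial_span))
    if (mvo$extent_deg > lesion_extent_deg ||
        mvo$radial_span[2] > transmural_mean - transmural_amplitude ||
        mvo$radial_span[1] < 0 || mvo$radial_span[1] >= mvo$radial_span[2])
      stop("infeasible geometry: MVO core lies outside the lesion", call. = FALSE)
  }
  structure(list(shape = as.integer(shape), pixel_spacing = pixel_spacing,
                 center = center, endo_radius_mm = endo_radius_mm,
                 epi_radius_mm = epi_radius_mm,
                 lesion_center_deg = lesion_center_deg,
                 lesion_extent_deg = lesion_extent_deg,
                 transmural_mean = transmural_mean,
                 transmural_amplitude = transmural_amplitude,
                 pse = pse, mvo = mvo,
                 remote_intensity = remote_intensity,
                 lesion_intensity = lesion_intensity,
                 blood_intensity = blood_intensity,
                 background_intensity = background_intensity,
                 mvo_intensity = mvo_intensity,
                 noise = noise, target_cnr = target_cnr, noise_sd = noise_sd,
                 seed = as.integer(seed), n_slices = as.integer(n_slices),
                 slice_spacing = slice_spacing),
            class = "lge_phantom_spec")
}

#' Generate a synthetic LGE phantom
#'
#' Builds the noiseless tissue geometry from an [phantom_spec()] — the truth
#' label map is decided before any noise is injected — then adds seeded
#' noise: additive Gaussian, or Rician as the magnitude of the signal plus
#' complex Gaussian noise. The noise SD is `(lesion - remote) / target_cnr`
#' when a target CNR is requested. The transmural fraction of the wedge
#' varies sinusoidally about its mean with one full period across the wedge.
#'
#' @param spec An [phantom_spec()].
#' @return An object of class `lge_phantom`: list with `stack`
#'   ([image_stack()]), `truth` (list of `lge_label_map` per slice), and
#'   `truth_record` — a one-row tibble with the true lesion / MVO / infarct
#'   areas (mm^2, per slice), the user-set mean transmurality, the per-slice
#'   ESL (%), the injected noise SD and the realized CNR measured on the
#'   first slice with the truth masks (`NA` when noiseless).
#' @export
#' @examples
#' ph <- generate_phantom(phantom_spec(target_cnr = 8, seed = 42))
#' ph$truth_record$lesion_area_mm2
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "lge_phantom_spec"))
  px_mm <- mean(spec$pixel_spacing)
  th <- pixel_angles(spec$shape, spec$center)
  rad_mm <- pixel_radii(spec$shape, spec$center) * px_mm

  myo <- rad_mm > spec$endo_radius_mm & rad_mm <= spec$epi_radius_mm
  cavity <- rad_mm <= spec$endo_radius_mm
  ctr <- spec$lesion_center_deg * pi / 180
  half <- spec$lesion_extent_deg / 2 * pi / 180
  dth <- ((th - ctr + pi) %% (2 * pi)) - pi
  in_wedge <- abs(dth) <= half
  # transmural fraction: one sine period across the wedge, mean preserved
  f <- spec$transmural_mean + spec$transmural_amplitude *
    sin(pi * (dth + half) / half)
  f <- pmin(pmax(f, 0), 1)
  wall <- spec$epi_radius_mm - spec$endo_radius_mm
  lesion <- myo & in_wedge & rad_mm <= spec$endo_radius_mm + f * wall

  mvo <- matrix(FALSE, spec$shape[1], spec$shape[2])
  if (!is.null(spec$mvo)) {
    mh <- spec$mvo$extent_deg / 2 * pi / 180
    mvo <- lesion & abs(dth) <= mh &
      rad_mm > spec$endo_radius_mm + spec$mvo$radial_span[1] * wall &
      rad_mm <= spec$endo_radius_mm + spec$mvo$radial_span[2] * wall
  }

  base <- matrix(spec$background_intensity, spec$shape[1], spec$shape[2])
  base[cavity] <- spec$blood_intensity
  base[myo] <- spec$remote_intensity
  base[lesion] <- spec$lesion_intensity
  base[mvo] <- spec$mvo_intensity

  labels <- matrix(LABEL_OUTSIDE, spec$shape[1], spec$shape[2])
  labels[myo] <- LABEL_REMOTE
  labels[lesion] <- LABEL_LESION
  labels[mvo] <- LABEL_MVO

  sd_n <- if (!is.null(spec$target_cnr))
    (spec$lesion_intensity - spec$remote_intensity) / spec$target_cnr
  else if (!is.null(spec$noise_sd)) spec$noise_sd else 0

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(spec$seed)
  npx <- prod(spec$shape)
  slices <- lapply(seq_len(spec$n_slices), function(i) {
    if (sd_n == 0) return(base)
    if (spec$noise == "gaussian") {
      base + matrix(rnorm(npx, 0, sd_n), spec$shape[1], spec$shape[2])
    } else {
      n1 <- matrix(rnorm(npx, 0, sd_n), spec$shape[1], spec$shape[2])
      n2 <- matrix(rnorm(npx, 0, sd_n), spec$shape[1], spec$shape[2])
      sqrt((base + n1)^2 + n2^2)
    }
  })

  stack <- image_stack(slices, spec$pixel_spacing, spec$slice_spacing)
  truth <- lapply(seq_len(spec$n_slices), function(i)
    label_map(labels, "truth", list(seed = spec$seed)))

  px_area <- prod(spec$pixel_spacing)
  realized <- tryCatch(
    measure_cnr(slices[[1]], lesion & !mvo, myo & !lesion),
    error = function(e) NA_real_)
  record <- tibble::tibble(
    lesion_area_mm2 = sum(lesion & !mvo) * px_area,
    mvo_area_mm2 = sum(mvo) * px_area,
    infarct_area_mm2 = sum(lesion) * px_area,
    n_lesion_px = sum(lesion & !mvo), n_mvo_px = sum(mvo),
    mean_transmurality = spec$transmural_mean,
    esl_percent = spec$lesion_extent_deg / 360 * 100,
    noise_sd = sd_n, realized_cnr = realized,
    target_cnr = if (is.null(spec$target_cnr)) NA_real_ else spec$target_cnr)

  structure(list(stack = stack, truth = truth, truth_record = record,
                 spec = spec),
            class = "lge_phantom")
}

#' @export
print.lge_phantom <- function(x, ...) {
  cat(sprintf("<lge_phantom> %d slice(s), infarct %.0f mm^2 (lesion %.0f + MVO %.0f), noise sd %.3g, realized CNR %.3g\n",
              n_slices(x$stack), x$truth_record$infarct_area_mm2,
              x$truth_record$lesion_area_mm2, x$truth_record$mvo_area_mm2,
              x$truth_record$noise_sd, x$truth_record$realized_cnr))
  invisible(x)
}

#' Measure the contrast-to-noise ratio
#'
#' CNR = (mean lesion intensity - mean remote intensity) / SD of the signal
#' intensity in the (remote, healthy) myocardium. Population SD, consistent
#' with the rest of the package. A negative CNR (lesion darker than remote)
#' is returned as-is.
#'
#' @param image Intensity matrix.
#' @param lesion_mask,remote_mask Nonempty logical masks.
#' @return CNR (scalar). Errors when the remote SD is zero (noiseless image:
#'   CNR undefined/infinite).
#' @export
#' @examples
#' img <- matrix(c(rep(100, 8), rep(180, 8)), 4, 4)
#' # measure_cnr on noiseless regions errors (zero remote SD)
measure_cnr <- function(image, lesion_mask, remote_mask) {
  if (!any(lesion_mask) || !any(remote_mask))
    stop("both masks must be nonempty", call. = FALSE)
  vr <- image[as.logical(remote_mask)]
  sdr <- sqrt(sum((vr - mean(vr))^2) / length(vr))
  if (sdr == 0)
    stop("zero remote SD: CNR undefined/infinite on a noiseless image",
         call. = FALSE)
  (mean(image[as.logical(lesion_mask)]) - mean(vr)) / sdr
}
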