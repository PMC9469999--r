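# Myocardial segmentation: polar B-spline active contours (BEAS family),
# two-click initialization, mm offsets and inter-slice propagation.

# --- periodic cubic B-spline machinery --------------------------------------

bspline3 <- function(t) {
  a <- abs(t)
  ifelse(a < 1, (4 - 6 * a^2 + 3 * a^3) / 6,
         ifelse(a < 2, (2 - a)^3 / 6, 0))
}

# Basis matrix of a uniform periodic cubic B-spline over [0, 2*pi).
periodic_basis <- function(theta, n_knots) {
  u <- theta / (2 * pi / n_knots)
  M <- matrix(0, length(theta), n_knots)
  for (k in seq_len(n_knots)) {
    d <- (u - (k - 1)) %% n_knots
    d <- ifelse(d > n_knots / 2, d - n_knots, d)
    M[, k] <- bspline3(d)
  }
  M
}

#' Polar contour with periodic B-spline radius
#'
#' A closed contour represented as a strictly positive radius function of
#' angle about a center point, encoded by coefficients of a uniform periodic
#' cubic B-spline. This is the native representation of the active-contour
#' myocardial segmentation and of inter-slice propagation.
#'
#' @param center `(row, col)` center in pixel coordinates.
#' @param coef Numeric B-spline coefficients (one per knot).
#' @param n_knots Number of uniform knots over the circle.
#' @return An object of class `lge_polar_contour`.
#' @export
polar_contour <- function(center, coef, n_knots = length(coef)) {
  stopifnot(length(coef) == n_knots, n_knots >= 4)
  pc <- structure(list(center = as.numeric(center), coef = as.numeric(coef),
                       n_knots = as.integer(n_knots)),
                  class = "lge_polar_contour")
  if (any(radius_at(pc, seq(0, 2 * pi, length.out = 256)) <= 0))
    stop("polar contour radius must be strictly positive", call. = FALSE)
  pc
}

#' @rdname polar_contour
#' @param pc An `lge_polar_contour`.
#' @param theta Angles (radians).
#' @export
radius_at <- function(pc, theta) {
  as.numeric(periodic_basis(theta %% (2 * pi), pc$n_knots) %*% pc$coef)
}

#' @rdname polar_contour
#' @param n Number of vertices to sample.
#' @return `as_contour()`: an [contour()] sampled counterclockwise.
#' @export
as_contour.lge_polar_contour <- function(pc, n = 96) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  r <- radius_at(pc, th)
  contour(cbind(row = pc$center[1] - r * sin(th),
                col = pc$center[2] + r * cos(th)))
}

#' @rdname polar_contour
#' @export
as_contour <- function(pc, n = 96) UseMethod("as_contour")

# Fit a polar B-spline to a vertex contour (least squares on sampled radii).
as_polar_contour <- function(ct, center = NULL, n_knots = 12) {
  v <- as.matrix(unclass(ct))
  if (is.null(center)) center <- colMeans(v)
  th <- (atan2(-(v[, 1] - center[1]), v[, 2] - center[2]) + 2 * pi) %% (2 * pi)
  r <- sqrt((v[, 1] - center[1])^2 + (v[, 2] - center[2])^2)
  M <- periodic_basis(th, n_knots)
  coef <- solve(crossprod(M) + 1e-8 * diag(n_knots), crossprod(M, r))
  polar_contour(center, as.numeric(coef), n_knots)
}

# --- initialization ---------------------------------------------------------

#' Two-click LV template initialization
#'
#' Builds a single-slice LV segmentation from two clicks: the LV center and a
#' point on the epicardial border. The epicardial contour is the circle
#' through the second click centered at the first; the endocardial contour is
#' a concentric circle at `endo_fraction` of the epicardial radius.
#'
#' @param center_click,epi_click `(row, col)` points; must be distinct.
#' @param shape Optional grid shape used to validate that `epi_click` lies
#'   inside the image.
#' @param endo_fraction Endocardial/epicardial radius ratio (default 0.6).
#' @param n_knots B-spline knots for the polar representation.
#' @return An `lge_lv_seg` carrying polar representations in `$polar`.
#' @export
#' @examples
#' seg <- init_lv_template(c(64, 64), c(64, 94))
#' radius_at(seg$polar$epi, 0)  # 30
init_lv_template <- function(center_click, epi_click, shape = NULL,
                             endo_fraction = 0.6, n_knots = 12) {
  r_epi <- sqrt(sum((center_click - epi_click)^2))
  if (r_epi == 0) stop("clicks must be distinct", call. = FALSE)
  if (!is.null(shape) &&
      (any(epi_click < 1) || epi_click[1] > shape[1] || epi_click[2] > shape[2]))
    stop("epicardial click lies outside the image", call. = FALSE)
  pc_epi <- polar_contour(center_click, rep(r_epi, n_knots))
  pc_endo <- polar_contour(center_click, rep(r_epi * endo_fraction, n_knots))
  seg <- lv_segmentation(as_contour(pc_epi), as_contour(pc_endo))
  seg$polar <- list(epi = pc_epi, endo = pc_endo)
  seg
}

#' Active-contour evolution parameters
#'
#' @param max_iterations Maximum descent iterations.
#' @param step_px Maximum radial move per iteration (pixels).
#' @param localization_mm Radial half-width of the local in/out bands (mm).
#' @param tol_px Convergence tolerance on the mean absolute radial change.
#' @param n_angles Angular samples along each contour.
#' @return A list of class `lge_beas_params`.
#' @export
beas_params <- function(max_iterations = 200, step_px = 0.5,
                        localization_mm = 4, tol_px = 0.02, n_angles = 72) {
  stopifnot(max_iterations >= 1, step_px > 0, localization_mm > 0,
            tol_px > 0, tol_px < 1, n_angles >= 16)
  structure(list(max_iterations = max_iterations, step_px = step_px,
                 localization_mm = localization_mm, tol_px = tol_px,
                 n_angles = n_angles), class = "lge_beas_params")
}

# Local band energy of one polar contour: squared residuals against the
# local inside/outside means along each ray (Yezzi-style localized means).
local_band <- function(image, pc, theta, s) {
  r <- radius_at(pc, theta)
  rin <- outer(r, s, "-"); rout <- outer(r, s, "+")
  rows_in <- pc$center[1] - rin * sin(theta); cols_in <- pc$center[2] + rin * cos(theta)
  rows_out <- pc$center[1] - rout * sin(theta); cols_out <- pc$center[2] + rout * cos(theta)
  Iin <- matrix(bilinear(image, rows_in, cols_in), length(theta))
  Iout <- matrix(bilinear(image, rows_out, cols_out), length(theta))
  u_in <- rowMeans(Iin); u_out <- rowMeans(Iout)
  Ib <- bilinear(image, pc$center[1] - r * sin(theta), pc$center[2] + r * cos(theta))
  # localized-mean-separation energy: minimized when each ray's boundary
  # sits on the edge separating homogeneous local bands
  list(r = r, u_in = u_in, u_out = u_out, Ib = Ib,
       energy = -sum((u_in - u_out)^2))
}

#' Evolve the myocardial contours by localized region energy descent
#'
#' Refines the epicardial and endocardial polar B-spline contours of an
#' initial LV segmentation by gradient descent on a localized region energy:
#' at each angular sample the boundary separates a local inside band from a
#' local outside band along the ray, and the boundary speed is the difference
#' of squared residuals against the two local band means. Radial updates are
#' projected back onto the periodic B-spline basis each iteration, the
#' endocardial contour is clipped strictly inside the epicardial one, and a
#' joint backtracking step guarantees the energy never increases across
#' accepted iterations. Terminates when the mean absolute radial change drops
#' below `tol_px` or at `max_iterations` (non-convergence returns the best
#' iterate with `converged = FALSE`, never an error).
#'
#' @param image 2D intensity matrix.
#' @param init An `lge_lv_seg` (from [init_lv_template()] or with `$polar`).
#' @param params An [beas_params()] list.
#' @param pixel_spacing mm per pixel, used to convert the localization
#'   radius to pixels.
#' @return An `lge_lv_seg` with attributes `converged` (logical),
#'   `iterations`, and `energy` (trace across accepted iterations).
#' @export
evolve_beas <- function(image, init, params = beas_params(),
                        pixel_spacing = c(1, 1)) {
  if (length(pixel_spacing) == 1) pixel_spacing <- rep(pixel_spacing, 2)
  if (is.null(init$polar))
    init$polar <- list(epi = as_polar_contour(init$epi),
                       endo = as_polar_contour(init$endo))
  epi <- init$polar$epi; endo <- init$polar$endo
  theta <- seq(0, 2 * pi, length.out = params$n_angles + 1)[-(params$n_angles + 1)]
  rho <- max(1, params$localization_mm / mean(pixel_spacing))
  s <- seq(0.5, rho, by = 0.5)
  M <- periodic_basis(theta, epi$n_knots)
  proj <- solve(crossprod(M) + 1e-8 * diag(epi$n_knots)) %*% t(M)

  fit_coef <- function(r) as.numeric(proj %*% r)
  energy_of <- function(e, d)
    local_band(image, e, theta, s)$energy + local_band(image, d, theta, s)$energy

  E <- energy_of(epi, endo)
  energies <- E
  converged <- FALSE
  it <- 0
  while (it < params$max_iterations) {
    it <- it + 1
    be <- local_band(image, epi, theta, s)
    bd <- local_band(image, endo, theta, s)
    speed <- function(b) {
      g <- (b$Ib - b$u_in)^2 - (b$Ib - b$u_out)^2
      -g / (max(abs(g)) + 1e-12) * params$step_px
    }
    de <- speed(be); dd <- speed(bd)
    scale <- 1
    accepted <- FALSE
    for (half in 0:6) {
      re <- pmax(be$r + scale * de, 2)
      rd <- pmax(bd$r + scale * dd, 1)
      rd <- pmin(rd, re - 1)  # endo strictly inside epi
      epi2 <- polar_contour(epi$center, fit_coef(re))
      endo2 <- polar_contour(endo$center, fit_coef(rd))
      E2 <- energy_of(epi2, endo2)
      if (E2 <= E + 1e-9) { accepted <- TRUE; break }
      scale <- scale / 2
    }
    if (!accepted) break
    dmean <- mean(c(abs(re - be$r), abs(rd - bd$r)))
    epi <- epi2; endo <- endo2; E <- E2
    energies <- c(energies, E)
    if (dmean < params$tol_px) { converged <- TRUE; break }
  }
  out <- lv_segmentation(as_contour(epi, params$n_angles),
                         as_contour(endo, params$n_angles),
                         rv_insertion = init$rv_insertion,
                         endo_offset_mm = init$endo_offset_mm,
                         epi_offset_mm = init$epi_offset_mm)
  out$polar <- list(epi = epi, endo = endo)
  attr(out, "converged") <- converged || it < params$max_iterations
  attr(out, "iterations") <- it
  attr(out, "energy") <- energies
  out
}

#' Myocardial mask from an LV segmentation
#'
#' Rasterizes the band between the epicardial and endocardial contours and
#' erodes it by `epi_offset_mm` from the epicardial side and `endo_offset_mm`
#' from the endocardial side (offsets converted to pixels via the spacing and
#' rounded to the nearest pixel).
#'
#' @param seg An `lge_lv_seg`.
#' @param shape Grid shape `c(nrow, ncol)`.
#' @param pixel_spacing mm per pixel.
#' @return Logical myocardium mask. Errors with "empty myocardium" when the
#'   offsets consume the whole band.
#' @export
myocardium_mask <- function(seg, shape, pixel_spacing = c(1, 1)) {
  if (length(pixel_spacing) == 1) pixel_spacing <- rep(pixel_spacing, 2)
  px <- mean(pixel_spacing)
  inside_epi <- rasterize_contour(seg$epi, shape)
  inside_endo <- rasterize_contour(seg$endo, shape)
  k_epi <- round(seg$epi_offset_mm / px)
  k_endo <- round(seg$endo_offset_mm / px)
  band <- erode_disc(inside_epi, k_epi) & !dilate_disc(inside_endo, k_endo)
  if (!any(band))
    stop("empty myocardium: offsets consume the whole band", call. = FALSE)
  band
}

#' Propagate keyed contours across a stack
#'
#' Given LV segmentations keyed on a subset of slices (typically one basal,
#' one mid and one apical slice), fills every intermediate slice by linear
#' interpolation of the polar representations — center and B-spline radius
#' coefficients — by slice index. Keyed slices are returned unchanged; slices
#' outside the keyed range copy the nearest key. A single keyed slice is
#' copied to all slices.
#'
#' @param stack An [image_stack()] (or an integer slice count).
#' @param keyed Named list of `lge_lv_seg` objects; names are slice indices.
#' @return List of `lge_lv_seg`, one per slice.
#' @export
propagate_contours <- function(stack, keyed) {
  n <- if (inherits(stack, "lge_image_stack")) n_slices(stack) else as.integer(stack)
  idx <- as.integer(names(keyed))
  stopifnot(length(idx) >= 1, all(idx >= 1), all(idx <= n))
  ord <- order(idx); idx <- idx[ord]; keyed <- keyed[ord]
  keyed <- lapply(keyed, function(s) {
    if (is.null(s$polar))
      s$polar <- list(epi = as_polar_contour(s$epi), endo = as_polar_contour(s$endo))
    s
  })
  interp_seg <- function(a, b, w) {
    lerp <- function(x, y) (1 - w) * x + w * y
    pe <- polar_contour(lerp(a$polar$epi$center, b$polar$epi$center),
                        lerp(a$polar$epi$coef, b$polar$epi$coef))
    pd <- polar_contour(lerp(a$polar$endo$center, b$polar$endo$center),
                        lerp(a$polar$endo$coef, b$polar$endo$coef))
    rv <- if (!is.null(a$rv_insertion) && !is.null(b$rv_insertion))
      lerp(a$rv_insertion, b$rv_insertion) else a$rv_insertion
    out <- lv_segmentation(as_contour(pe), as_contour(pd), rv_insertion = rv,
                           endo_offset_mm = lerp(a$endo_offset_mm, b$endo_offset_mm),
                           epi_offset_mm = lerp(a$epi_offset_mm, b$epi_offset_mm))
    out$polar <- list(epi = pe, endo = pd)
    out
  }
  lapply(seq_len(n), function(i) {
    if (i %in% idx) return(keyed[[match(i, idx)]])
    if (length(idx) == 1 || i < idx[1]) return(keyed[[1]])
    if (i > idx[length(idx)]) return(keyed[[length(idx)]])
    j <- findInterval(i, idx)
    interp_seg(keyed[[j]], keyed[[j + 1]],
               (i - idx[j]) / (idx[j + 1] - idx[j]))
  })
}
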