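# Hyperenhancement (infarct) segmentation methods and MVO handling.
#
# All methods label pixels *within the myocardium*. The boundary rule is
# fixed package-wide: a pixel is lesion when its intensity is strictly
# greater than the threshold T (the interactive range method is inclusive on
# both cursors, documented in its help page).

new_threshold_result <- function(threshold, lesion, method, params,
                                 flags = character()) {
  structure(list(threshold = threshold, lesion = lesion, method = method,
                 params = params, flags = flags),
            class = "lge_threshold")
}

#' @export
print.lge_threshold <- function(x, ...) {
  cat(sprintf("<lge_threshold> %s: T = %.4g, %d lesion pixel(s)%s\n",
              x$method, x$threshold, sum(x$lesion),
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]") else ""))
  invisible(x)
}

#' @method tidy lge_threshold
#' @export
tidy.lge_threshold <- function(x, ...) {
  tibble::tibble(method = x$method, threshold = x$threshold,
                 n_lesion = sum(x$lesion),
                 flags = paste(x$flags, collapse = ";"))
}

#' n-SD signal threshold versus reference mean (STRM)
#'
#' Thresholds the myocardium at `T = mu + c * sigma`, where `mu` and `sigma`
#' are the mean and (population) SD of the remote healthy reference region
#' and `c` is a positive integer, usually between 2 and 10. Pixels strictly
#' above `T` are lesion.
#'
#' @param image Intensity matrix.
#' @param myo_mask Logical myocardium mask.
#' @param remote_mask Logical remote-reference mask (nonempty).
#' @param c Threshold multiplier; a warning is raised outside `[2, 10]`.
#' @param pixel_spacing mm per pixel (propagated into statistics).
#' @return An `lge_threshold` with elements `threshold`, `lesion`, `method`,
#'   `params`.
#' @export
#' @examples
#' img <- matrix(c(100, 100, 151, 150), 2, 2)
#' m <- matrix(TRUE, 2, 2)
#' r <- threshold_nsd(img, m, matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2), c = 5)
threshold_nsd <- function(image, myo_mask, remote_mask, c = 5,
                          pixel_spacing = rep(1, 2)) {
  if (!any(remote_mask)) stop("empty remote region", call. = FALSE)
  if (c < 1) stop("c must be a positive integer", call. = FALSE)
  if (c < 2 || c > 10)
    warning("c is usually between 2 and 10", call. = FALSE)
  st <- region_stats(image, remote_mask, pixel_spacing)
  T <- st$mean + c * st$sd
  new_threshold_result(T, as.logical(myo_mask) & image > T,
                       sprintf("%d-SD", as.integer(c)),
                       list(c = c, mu = st$mean, sigma = st$sd))
}

#' Interactive histogram range threshold
#'
#' Labels myocardial pixels whose intensity lies in the closed interval
#' `[lo, hi]` — the two interactive histogram cursors. Note the boundary
#' convention: both ends are inclusive, whereas the computed-threshold
#' methods use a strict `> T`.
#'
#' @inheritParams threshold_nsd
#' @param lo,hi Intensity cursors, `lo < hi`.
#' @export
threshold_range <- function(image, myo_mask, lo, hi) {
  if (lo >= hi) stop("lo must be strictly below hi", call. = FALSE)
  new_threshold_result(lo, as.logical(myo_mask) & image >= lo & image <= hi,
                       "range", list(lo = lo, hi = hi))
}

#' Full-width at half-maximum threshold
#'
#' Thresholds at `T = I_max / 2`. In `"max"` mode `I_max` is the maximum
#' intensity within the myocardium; in `"region"` mode it is the maximum of
#' the 3x3-mean-smoothed intensity within a user seed region (intersected
#' with the myocardium), which damps single noisy maxima.
#'
#' @inheritParams threshold_nsd
#' @param mode `"max"` or `"region"`.
#' @param seed_region Logical mask (required in region mode; must intersect
#'   the myocardium).
#' @export
threshold_fwhm <- function(image, myo_mask, mode = c("max", "region"),
                           seed_region = NULL) {
  mode <- match.arg(mode)
  myo_mask <- as.logical(myo_mask); dim(myo_mask) <- dim(image)
  if (!any(myo_mask)) stop("empty myocardium", call. = FALSE)
  if (mode == "max") {
    imax <- max(image[myo_mask])
  } else {
    if (is.null(seed_region) || !any(seed_region & myo_mask))
      stop("region mode needs a seed region intersecting the myocardium",
           call. = FALSE)
    sm <- EBImage::filter2(image, matrix(1 / 9, 3, 3), boundary = "replicate")
    imax <- max(sm[as.logical(seed_region) & myo_mask])
  }
  T <- imax / 2
  new_threshold_result(T, myo_mask & image > T,
                       paste0("FWHM-", mode), list(imax = imax, mode = mode))
}

# --- Rician-Gaussian mixture -------------------------------------------------

# log I0(z): exponentially scaled Bessel for moderate z, asymptotic
# expansion for large z (base besselI underflows above ~1e5).
log_bessel_i0 <- function(z) {
  out <- numeric(length(z))
  small <- z < 50
  if (any(small))
    out[small] <- log(besselI(z[small], 0, expon.scaled = TRUE)) + z[small]
  if (any(!small)) {
    zb <- z[!small]
    out[!small] <- zb - 0.5 * log(2 * pi * zb) +
      log1p(1 / (8 * zb) + 9 / (128 * zb^2))
  }
  out
}

# I1(z)/I0(z), with the asymptotic form where base besselI loses precision.
bessel_ratio_a <- function(z) {
  out <- numeric(length(z))
  small <- z < 50
  if (any(small))
    out[small] <- besselI(z[small], 1, expon.scaled = TRUE) /
      besselI(z[small], 0, expon.scaled = TRUE)
  if (any(!small)) {
    zb <- z[!small]
    out[!small] <- 1 - 1 / (2 * zb) - 1 / (8 * zb^2)
  }
  out
}

# log density of the Rice distribution.
drice_log <- function(x, nu, sigma) {
  s2 <- sigma^2
  z <- x * nu / s2
  log(pmax(x, .Machine$double.xmin)) - log(s2) - (x^2 + nu^2) / (2 * s2) +
    log_bessel_i0(z)
}

rice_mean <- function(nu, sigma) {
  # numeric moment (stable for all SNR)
  x <- seq(0, nu + 12 * sigma, length.out = 4096)
  dx <- x[2] - x[1]
  sum(x * exp(drice_log(pmax(x, 1e-12), nu, sigma))) * dx
}

#' Rician-Gaussian mixture threshold
#'
#' Fits a two-component mixture `w * Rice(nu, sigma_r) + (1 - w) *
#' N(mu_g, sigma_g^2)` to the myocardial intensity histogram by EM — the
#' Rician component models the healthy (remote) myocardium of a magnitude MR
#' image, the Gaussian the enhanced lesion — and thresholds at the abscissa
#' where the two weighted component densities cross between the component
#' modes. If no crossing exists in that interval the equal-posterior point of
#' closest approach is used and the result is flagged `"no_crossing"`.
#'
#' Initialization is a deterministic 2-means split of the intensities
#' (centers at the 25% and 75% quantiles), so the fit is reproducible; the
#' Rician M-step has no closed form and is solved by a fixed-point
#' iteration on `nu` with bounded inner iterations.
#'
#' @inheritParams threshold_nsd
#' @param tol EM convergence tolerance on the mean log-likelihood.
#' @param max_iter Maximum EM iterations; non-convergence returns the best
#'   iterate flagged `"no_converge"`.
#' @param seed Optional integer seed (the default path consumes no
#'   randomness; the seed is set and restored for reproducibility of any
#'   stochastic extension).
#' @return A list of class `lge_mixture_fit` with the component parameters,
#'   weight, log-likelihood, `threshold`, `flags`, and the `lge_threshold`
#'   result in `$result`.
#' @export
fit_rician_gaussian <- function(image, myo_mask, tol = 1e-6, max_iter = 200,
                                seed = NULL) {
  x <- image[as.logical(myo_mask)]
  if (length(x) < 50) stop("need at least 50 myocardial pixels", call. = FALSE)
  if (any(x < 0)) stop("negative intensities: Rician support is nonnegative",
                       call. = FALSE)
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  x <- pmax(x, 1e-6)
  flags <- character()

  # deterministic 2-means initialization
  cen <- matrix(quantile(x, c(0.25, 0.75)), ncol = 1)
  if (abs(cen[2] - cen[1]) < 1e-9) cen <- matrix(range(x), ncol = 1)
  if (diff(range(x)) < 1e-9) {
    km_lab <- rep(1L, length(x))
  } else {
    km <- suppressWarnings(kmeans(x, centers = cen, iter.max = 50))
    km_lab <- if (km$centers[1] <= km$centers[2]) km$cluster else 3L - km$cluster
  }
  lo <- x[km_lab == 1]; hi <- x[km_lab == 2]
  if (length(hi) < 2) { hi <- x[x >= quantile(x, 0.9)]; lo <- x }
  sfloor <- max(1e-3, 1e-4 * diff(range(x)))
  m1 <- mean(lo); s1 <- max(sd(lo), sfloor)
  nu <- sqrt(max(m1^2 - s1^2, (0.1 * m1)^2))
  sig_r <- s1
  mu_g <- mean(hi); sig_g <- max(sd(hi), sfloor)
  w <- length(lo) / length(x)
  w <- min(max(w, 1e-3), 1 - 1e-3)

  ll_old <- -Inf; converged <- FALSE
  for (it in seq_len(max_iter)) {
    lr <- drice_log(x, nu, sig_r) + log(w)
    lg <- dnorm(x, mu_g, sig_g, log = TRUE) + log(1 - w)
    mx <- pmax(lr, lg)
    den <- mx + log(exp(lr - mx) + exp(lg - mx))
    ll <- mean(den)
    g_r <- exp(lr - den)             # responsibility of the Rician component
    w <- min(max(mean(g_r), 1e-6), 1 - 1e-6)
    sw <- sum(1 - g_r)
    if (sw > 1e-8) {
      mu_g <- sum((1 - g_r) * x) / sw
      sig_g <- max(sqrt(sum((1 - g_r) * (x - mu_g)^2) / sw), sfloor)
    }
    # Rician M-step has no closed form: fixed-point iteration on nu with
    # bounded inner iterations (phase treated as missing data; A = I1/I0).
    sw_r <- sum(g_r)
    if (sw_r > 1e-8) {
      m2 <- sum(g_r * x^2) / sw_r
      for (k in seq_len(5)) {
        A <- bessel_ratio_a(x * nu / sig_r^2)
        nu_new <- max(sum(g_r * x * A) / sw_r, 0)
        sig_r <- sqrt(max((m2 - nu_new^2) / 2, sfloor^2))
        if (abs(nu_new - nu) < 1e-8 * (nu + 1)) { nu <- nu_new; break }
        nu <- nu_new
      }
    }
    if (is.finite(ll) && abs(ll - ll_old) < tol) { converged <- TRUE; break }
    ll_old <- ll
  }
  if (!converged) flags <- c(flags, "no_converge")
  if (w < 0.01 || w > 0.99) flags <- c(flags, "degenerate")

  # threshold: crossing of the weighted component densities between modes
  mode_r <- rice_mode(nu, sig_r)
  lo_b <- min(mode_r, mu_g); hi_b <- max(mode_r, mu_g)
  if (hi_b - lo_b < 1e-9) { lo_b <- lo_b - sfloor; hi_b <- hi_b + sfloor }
  grid <- seq(lo_b, hi_b, length.out = 2048)
  diffd <- (drice_log(pmax(grid, 1e-9), nu, sig_r) + log(w)) -
    (dnorm(grid, mu_g, sig_g, log = TRUE) + log(1 - w))
  sgn <- sign(diffd)
  cross <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  if (length(cross)) {
    i <- cross[length(cross)]  # crossing nearest the Gaussian mode
    threshold <- (grid[i] + grid[i + 1]) / 2
  } else {
    threshold <- grid[which.min(abs(diffd))]
    flags <- c(flags, "no_crossing")
  }
  res <- new_threshold_result(threshold,
                              as.logical(myo_mask) & image > threshold,
                              "GMM", list(w = w, nu = nu, sigma_r = sig_r,
                                          mu_g = mu_g, sigma_g = sig_g),
                              flags)
  structure(list(w = w, nu = nu, sigma_r = sig_r, mu_g = mu_g,
                 sigma_g = sig_g, loglik = ll_old * length(x),
                 threshold = threshold, flags = flags, result = res,
                 n = length(x)),
            class = "lge_mixture_fit")
}

rice_mode <- function(nu, sigma) {
  x <- seq(1e-6, nu + 6 * sigma, length.out = 2048)
  x[which.max(drice_log(x, nu, sigma))]
}

#' @export
print.lge_mixture_fit <- function(x, ...) {
  cat(sprintf(
    "<lge_mixture_fit> w=%.3f Rice(nu=%.3g, sigma=%.3g) + %.3f N(%.3g, %.3g^2); T=%.4g%s\n",
    x$w, x$nu, x$sigma_r, 1 - x$w, x$mu_g, x$sigma_g, x$threshold,
    if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]") else ""))
  invisible(x)
}

#' @method tidy lge_mixture_fit
#' @export
tidy.lge_mixture_fit <- function(x, ...) {
  tibble::tibble(component = c("rician", "gaussian"),
                 weight = c(x$w, 1 - x$w),
                 location = c(x$nu, x$mu_g),
                 scale = c(x$sigma_r, x$sigma_g),
                 mean = c(rice_mean(x$nu, x$sigma_r), x$mu_g))
}

#' @method glance lge_mixture_fit
#' @export
glance.lge_mixture_fit <- function(x, ...) {
  tibble::tibble(threshold = x$threshold, loglik = x$loglik, n = x$n,
                 converged = !("no_converge" %in% x$flags),
                 crossing_found = !("no_crossing" %in% x$flags))
}

# --- FACT (Hsu modified) -----------------------------------------------------

#' FACT parameters
#'
#' @param initial_cutoff Multiplier for the initial `mu + cutoff * sigma`
#'   threshold (default 2).
#' @param min_region Minimum 8-connected lesion component size in pixels
#'   (default 10).
#' @param max_iter Maximum refinement iterations (default 10).
#' @return A list of class `lge_fact_params`.
#' @export
fact_params <- function(initial_cutoff = 2, min_region = 10, max_iter = 10) {
  stopifnot(min_region >= 1, max_iter >= 1, initial_cutoff > 0)
  structure(list(initial_cutoff = initial_cutoff, min_region = min_region,
                 max_iter = max_iter), class = "lge_fact_params")
}

#' Feature analysis and combined thresholding (Hsu modified)
#'
#' Iterative thresholding with regional false-positive elimination:
#' (1) threshold the myocardium at `mu + cutoff * sigma` of the remote
#' region; (2) remove 8-connected lesion components smaller than
#' `min_region` pixels; (3) only when the size filter removed something,
#' recompute the reference statistics on the myocardium minus the current
#' lesion and re-apply the threshold; repeat (2)-(3) until the lesion set is
#' stable or `max_iter` is reached; (4) promote enclosed hypointense pixels
#' to MVO via [detect_mvo()]. With `min_region = 1` nothing is ever removed,
#' so the result reduces to the initial threshold step plus MVO detection.
#'
#' @inheritParams threshold_nsd
#' @param params An [fact_params()] list.
#' @return An [label_map()] with classes remote/lesion/mvo inside the
#'   myocardium.
#' @export
hsu_fact <- function(image, myo_mask, remote_mask, params = fact_params(),
                     pixel_spacing = c(1, 1)) {
  if (!any(remote_mask)) stop("empty remote region", call. = FALSE)
  myo_mask <- as.logical(myo_mask); dim(myo_mask) <- dim(image)
  size_filter <- function(lesion) {
    if (!any(lesion)) return(lesion)
    lab <- conn_comp(lesion, 8)
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= params$min_region)
    lesion & matrix(lab %in% keep, nrow(lab), ncol(lab))
  }
  st <- region_stats(image, remote_mask, pixel_spacing)
  T <- st$mean + params$initial_cutoff * st$sd
  lesion <- myo_mask & image > T
  prev_filtered <- NULL
  for (it in seq_len(params$max_iter)) {
    filtered <- size_filter(lesion)
    removed <- sum(lesion) - sum(filtered)
    lesion <- filtered
    # stable when the size filter removed nothing, or the filtered set
    # reproduces itself across a re-estimation round
    if (removed == 0 || identical(filtered, prev_filtered)) break
    prev_filtered <- filtered
    ref <- myo_mask & !lesion
    if (!any(ref)) break
    st <- region_stats(image, ref, pixel_spacing)
    T <- st$mean + params$initial_cutoff * st$sd
    lesion <- myo_mask & image > T
  }
  lesion <- size_filter(lesion)
  labels <- matrix(LABEL_OUTSIDE, nrow(image), ncol(image))
  labels[myo_mask] <- LABEL_REMOTE
  labels[lesion] <- LABEL_LESION
  lm <- label_map(labels, "FACT", unclass(params))
  if (any(lesion)) {
    mvo <- detect_mvo(image, myo_mask, lesion)
    lm$labels[mvo] <- LABEL_MVO
  }
  lm
}

# --- HMRF-EM -----------------------------------------------------------------

#' HMRF-EM parameters
#'
#' @param beta Potts smoothness weight (>= 0, default 1).
#' @param neighborhood 4 or 8 (default 8).
#' @param max_iter Maximum EM iterations.
#' @param icm_sweeps ICM sweeps per E-step.
#' @param tol Convergence tolerance: fraction of myocardial labels changed
#'   between EM iterations.
#' @return A list of class `lge_hmrf_params`.
#' @export
hmrf_params <- function(beta = 1, neighborhood = 8, max_iter = 50,
                        icm_sweeps = 5, tol = 0.001) {
  stopifnot(beta >= 0, neighborhood %in% c(4, 8), max_iter >= 1,
            icm_sweeps >= 1, tol >= 0)
  structure(list(beta = beta, neighborhood = neighborhood,
                 max_iter = max_iter, icm_sweeps = icm_sweeps, tol = tol),
            class = "lge_hmrf_params")
}

#' Hidden Markov random field segmentation with EM
#'
#' Two-class (remote/lesion) labeling of the myocardium under a hidden
#' Markov random field: Gaussian emission per class (mean and SD estimated
#' in the M-step from the current labels) and a Potts spatial prior of
#' weight `beta` over the chosen neighborhood restricted to myocardial
#' pixels. The E-step approximates the MAP labeling by ICM sweeps (updated
#' in a 4-colour checkerboard order so each update sees current neighbor
#' labels); EM iterates until fewer than `tol` of the labels change.
#' Initialization defaults to a deterministic 2-means split of the
#' myocardial intensities. Enclosed hypointense pixels are promoted to MVO
#' afterwards via [detect_mvo()]. With `beta = 0` the labeling equals the
#' per-pixel Gaussian maximum-likelihood classification under the converged
#' parameters.
#'
#' @inheritParams threshold_nsd
#' @param params An [hmrf_params()] list.
#' @param init Optional initial `lge_label_map` (or logical lesion mask).
#' @return An [label_map()] with attribute `class_stats`: a tibble of the
#'   converged per-class mean and SD.
#' @export
hmrf_em <- function(image, myo_mask, params = hmrf_params(), init = NULL) {
  myo_mask <- as.logical(myo_mask); dim(myo_mask) <- dim(image)
  if (!any(myo_mask)) stop("empty myocardium", call. = FALSE)
  x_all <- image
  idx <- which(myo_mask)
  x <- x_all[idx]
  sfloor <- max(1e-6, 1e-6 * diff(range(x)))

  # initial labels: 1 = remote, 2 = lesion
  if (is.null(init)) {
    if (diff(range(x)) < 1e-12) {
      lab_v <- rep(1L, length(x))
    } else {
      cen <- matrix(quantile(x, c(0.25, 0.75)), ncol = 1)
      if (abs(cen[2] - cen[1]) < 1e-9) cen <- matrix(range(x), ncol = 1)
      km <- suppressWarnings(kmeans(x, centers = cen, iter.max = 50))
      lab_v <- if (km$centers[1] <= km$centers[2]) km$cluster else 3L - km$cluster
      lab_v <- as.integer(lab_v)
    }
  } else {
    les0 <- if (inherits(init, "lge_label_map")) class_mask(init, "lesion") else as.logical(init)
    lab_v <- ifelse(les0[idx], 2L, 1L)
  }

  offs <- neighbor_offsets(params$neighborhood)
  nr <- nrow(image); nc <- ncol(image)
  rr <- ((idx - 1) %% nr) + 1
  cc <- ((idx - 1) %/% nr) + 1
  color <- ((rr %% 2L) * 2L + (cc %% 2L)) + 1L  # 4-colour checkerboard

  lab_grid <- matrix(0L, nr, nc)   # 0 outside, 1 remote, 2 lesion
  lab_grid[idx] <- lab_v

  class_stats <- function(lab_v) {
    out <- matrix(0, 2, 2)
    for (l in 1:2) {
      v <- x[lab_v == l]
      if (length(v) == 0) { out[l, ] <- c(NA, NA); next }
      out[l, ] <- c(mean(v), max(sqrt(sum((v - mean(v))^2) / length(v)), sfloor))
    }
    out
  }

  warn_flag <- FALSE
  for (em in seq_len(params$max_iter)) {
    # M-step (and empty-class re-seed from the extreme decile)
    for (l in 1:2) {
      if (!any(lab_v == l)) {
        warn_flag <- TRUE
        q <- if (l == 2) x >= quantile(x, 0.9) else x <= quantile(x, 0.1)
        lab_v[q] <- l
        lab_grid[idx] <- lab_v
      }
    }
    cs <- class_stats(lab_v)
    lab_old <- lab_v
    # E-step: ICM sweeps
    for (sw in seq_len(params$icm_sweeps)) {
      for (col4 in 1:4) {
        sel <- color == col4
        if (!any(sel)) next
        # neighbor disagreement counts per candidate label
        n1 <- matrix(0, nr, nc); n2 <- matrix(0, nr, nc)
        for (k in seq_len(nrow(offs))) {
          sh <- shift_mat(lab_grid, offs[k, 1], offs[k, 2], fill = 0L)
          n1 <- n1 + (sh == 2L)   # neighbors disagreeing with label 1
          n2 <- n2 + (sh == 1L)
        }
        xs <- x[sel]
        e1 <- -dnorm(xs, cs[1, 1], cs[1, 2], log = TRUE) + params$beta * n1[idx[sel]]
        e2 <- -dnorm(xs, cs[2, 1], cs[2, 2], log = TRUE) + params$beta * n2[idx[sel]]
        lab_v[sel] <- ifelse(e2 < e1, 2L, 1L)
        lab_grid[idx] <- lab_v
      }
    }
    if (mean(lab_v != lab_old) <= params$tol && em > 1) break
  }
  cs <- class_stats(lab_v)

  labels <- matrix(LABEL_OUTSIDE, nr, nc)
  labels[idx] <- ifelse(lab_v == 2L, LABEL_LESION, LABEL_REMOTE)
  lm <- label_map(labels, "HMRF-EM", unclass(params))
  lesion <- lm$labels == LABEL_LESION
  if (any(lesion)) {
    mvo <- detect_mvo(image, myo_mask, lesion)
    lm$labels[mvo] <- LABEL_MVO
  }
  attr(lm, "class_stats") <- tibble::tibble(class = c("remote", "lesion"),
                                            mean = cs[, 1], sd = cs[, 2])
  attr(lm, "warning") <- warn_flag
  lm
}

# --- region growing and MVO --------------------------------------------------

#' Intensity-based region growing
#'
#' Grows the 8-connected set of pixels, inside a constraint mask, whose
#' intensity differs from the seed pixel's intensity by at most `tolerance`.
#'
#' @param image Intensity matrix.
#' @param seed `(row, col)` seed point (must lie in the constraint mask).
#' @param tolerance Maximum absolute intensity difference from the seed.
#' @param constraint Logical mask limiting the growth.
#' @return Logical mask of the grown region.
#' @export
region_grow <- function(image, seed, tolerance, constraint = NULL) {
  if (is.null(constraint)) constraint <- matrix(TRUE, nrow(image), ncol(image))
  constraint <- as.logical(constraint); dim(constraint) <- dim(image)
  seed <- as.integer(round(seed))
  if (!constraint[seed[1], seed[2]])
    stop("seed lies outside the constraint mask", call. = FALSE)
  ok <- constraint & abs(image - image[seed[1], seed[2]]) <= tolerance
  lab <- conn_comp(ok, 8)
  lab == lab[seed[1], seed[2]] & lab > 0
}

#' Detect microvascular obstruction (no-reflow) candidates
#'
#' Labels as MVO the 8-connected non-lesion myocardial components that are
#' enclosed by lesion and/or the endocardial boundary — i.e. that never touch
#' the region outside the epicardium — and whose mean intensity is below the
#' remote-myocardium mean. The cavity is recognised as the holes of the
#' myocardial mask, so a dark region touching the open remote wall is never
#' MVO.
#'
#' @inheritParams threshold_nsd
#' @param lesion_mask Logical lesion mask (nonempty).
#' @param remote_mean Optional reference mean; defaults to the mean of the
#'   non-lesion, non-candidate myocardium.
#' @return Logical MVO mask (possibly empty).
#' @export
detect_mvo <- function(image, myo_mask, lesion_mask, remote_mean = NULL) {
  myo_mask <- as.logical(myo_mask); dim(myo_mask) <- dim(image)
  lesion_mask <- as.logical(lesion_mask); dim(lesion_mask) <- dim(image)
  if (!any(lesion_mask)) stop("empty lesion mask", call. = FALSE)
  exterior <- !fill_holes(myo_mask)           # outside the epicardial border
  cand_src <- myo_mask & !lesion_mask
  if (!any(cand_src)) return(matrix(FALSE, nrow(image), ncol(image)))
  lab <- conn_comp(cand_src, 8)
  n_comp <- max(lab)
  enclosed <- rep(TRUE, n_comp)
  ext_ring <- dilate1(exterior)
  for (i in seq_len(n_comp)) {
    comp <- lab == i
    if (any(comp & ext_ring)) enclosed[i] <- FALSE
  }
  cand <- cand_src & matrix(enclosed[ifelse(lab > 0, lab, 1)] & lab > 0,
                            nrow(lab), ncol(lab))
  if (!any(cand)) return(cand)
  if (is.null(remote_mean)) {
    ref <- cand_src & !cand
    remote_mean <- if (any(ref)) mean(image[ref]) else mean(image[lesion_mask])
  }
  out <- matrix(FALSE, nrow(image), ncol(image))
  for (i in which(enclosed)) {
    comp <- lab == i
    if (mean(image[comp]) < remote_mean) out[comp] <- TRUE
  }
  out
}

#' Merge or remove an MVO region in a label map
#'
#' `action = "add"` assigns the pixels the MVO class, so the infarct size
#' (lesion + MVO area) grows accordingly; `action = "remove"` reverts
#' currently-MVO pixels of the mask to remote. The total myocardial pixel
#' count is conserved either way.
#'
#' @param labelmap An `lge_label_map`.
#' @param mvo_mask Logical mask, entirely within the myocardium.
#' @param action `"add"` or `"remove"`.
#' @return The updated `lge_label_map`.
#' @export
merge_mvo <- function(labelmap, mvo_mask, action = c("add", "remove")) {
  action <- match.arg(action)
  mvo_mask <- as.logical(mvo_mask); dim(mvo_mask) <- dim(labelmap$labels)
  if (any(mvo_mask & labelmap$labels == LABEL_OUTSIDE))
    stop("MVO mask overlaps pixels outside the myocardium", call. = FALSE)
  if (action == "add") {
    labelmap$labels[mvo_mask] <- LABEL_MVO
  } else {
    tgt <- mvo_mask & labelmap$labels == LABEL_MVO
    if (!any(tgt) && any(mvo_mask))
      warning("mask contains no MVO pixels; nothing removed", call. = FALSE)
    labelmap$labels[tgt] <- LABEL_REMOTE
  }
  labelmap
}

#' Infarct size of a label map
#'
#' Lesion + MVO pixel count (and area), the quantity reported as infarct
#' size: a detected MVO core is counted into the infarct.
#'
#' @param labelmap An `lge_label_map`.
#' @param pixel_spacing mm per pixel.
#' @return One-row tibble with `n_lesion`, `n_mvo`, `n_infarct`,
#'   `area_mm2`.
#' @export
infarct_size <- function(labelmap, pixel_spacing = c(1, 1)) {
  if (length(pixel_spacing) == 1) pixel_spacing <- rep(pixel_spacing, 2)
  nl <- sum(labelmap$labels == LABEL_LESION)
  nm <- sum(labelmap$labels == LABEL_MVO)
  tibble::tibble(n_lesion = nl, n_mvo = nm, n_infarct = nl + nm,
                 area_mm2 = (nl + nm) * pixel_spacing[1] * pixel_spacing[2])
}

#' Convert a threshold result to a label map
#'
#' @param x An `lge_threshold`.
#' @param myo_mask Logical myocardium mask.
#' @return An [label_map()] with remote/lesion classes.
#' @export
as_label_map <- function(x, myo_mask) {
  labels <- matrix(LABEL_OUTSIDE, nrow(x$lesion), ncol(x$lesion))
  labels[as.logical(myo_mask)] <- LABEL_REMOTE
  labels[x$lesion] <- LABEL_LESION
  label_map(labels, x$method, x$params)
}
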