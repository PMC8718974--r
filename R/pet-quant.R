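#' Extract a regional time-activity curve
#'
#' Per-frame unweighted mean of all voxels inside a binary mask.
#'
#' @param image a `dynamic_image`.
#' @param mask a `region_mask` on the same voxel grid.
#' @return A `tac`.
#' @export
extract_tac <- function(image, mask) {
  stopifnot(inherits(image, "dynamic_image"), inherits(mask, "region_mask"))
  d <- dim(image$data)
  if (!all(d[1:3] == dim(mask$data)))
    stop("geometry error: image and mask grids differ")
  if (!sum(mask$data)) stop("empty-region error: mask contains no voxels")
  sel <- which(mask$data)
  nf <- d[4]
  vox <- matrix(image$data, ncol = nf)[sel, , drop = FALSE]
  tac(image$schedule, colMeans(vox), region = mask$label)
}

#' Supervised reference-region extraction
#'
#' Identifies grey-matter voxels whose kinetics look like non-inflamed
#' grey matter.  Each grey-matter voxel's time course is normalized to
#' unit mean and decomposed by non-negative least squares onto a set of
#' normalized kinetic class curves; voxels whose (normalized) coefficient
#' on the `normal_grey` class exceeds `threshold` form the reference
#' mask, and the reference TAC is the plain mean curve over that mask.
#'
#' This is a deliberately lean re-expression of supervised-cluster
#' reference extraction: four canonical classes and a hard coefficient
#' threshold rather than the full published machinery.
#'
#' @param image a `dynamic_image`.
#' @param gm_mask grey-matter `region_mask`.
#' @param class_curves named list of normalized class `tac`s, one named
#'   `"normal_grey"` (see [kinetic_class_curves()]).
#' @param threshold minimum normalized grey coefficient (default 0.9).
#' @return List with `mask` (the reference `region_mask`), `tac`, and
#'   `coefficients` (voxels x classes matrix).
#' @export
supervised_reference <- function(image, gm_mask, class_curves, threshold = 0.9) {
  stopifnot(inherits(image, "dynamic_image"), inherits(gm_mask, "region_mask"))
  if (length(class_curves) < 2L || !"normal_grey" %in% names(class_curves))
    stop("need >= 2 kinetic classes including 'normal_grey'")
  d <- dim(image$data)
  if (!all(d[1:3] == dim(gm_mask$data)))
    stop("geometry error: image and mask grids differ")
  sel <- which(gm_mask$data)
  vox <- matrix(image$data, ncol = d[4])[sel, , drop = FALSE]
  A <- vapply(class_curves, function(ct) ct$activity, numeric(d[4]))
  coefs <- t(apply(vox, 1, function(v) {
    mu <- mean(v)
    if (mu <= 0) return(rep(0, ncol(A)))
    pracma::lsqnonneg(A, v / mu)$x
  }))
  colnames(coefs) <- names(class_curves)
  share <- coefs / pmax(rowSums(coefs), .Machine$double.eps)
  keep <- share[, "normal_grey"] >= threshold
  if (!any(keep))
    stop("empty-reference error: no grey-matter voxel passed the threshold")
  md <- array(FALSE, d[1:3])
  md[sel[keep]] <- TRUE
  mask <- region_mask(md, voxdim = image$voxdim, label = "supervised_reference")
  list(mask = mask, tac = extract_tac(image, mask), coefficients = coefs)
}

#' Late-window standardized uptake value ratio
#'
#' Mean target activity over a late window divided by mean reference
#' activity over the same window.  The default window is the final frame
#' (the "at 60 min" reading); `window` can instead give `c(t0, t1)` in
#' minutes, e.g. `c(50, 60)` for a late average.
#'
#' @param target,reference `tac`s on one schedule.
#' @param window NULL (final frame) or numeric `c(t0, t1)` in minutes.
#' @return Unitless SUVR.
#' @export
suvr_at_60 <- function(target, reference, window = NULL) {
  stopifnot(inherits(target, "tac"), inherits(reference, "tac"))
  sch <- target$schedule
  if (is.null(window)) {
    sel <- nrow(sch)
  } else {
    if (window[1] < min(sch$start) - 1e-9 || window[2] > max(sch$end) + 1e-9)
      stop("window error: window outside schedule")
    sel <- which(sch$mid >= window[1] & sch$mid <= window[2])
    if (!length(sel)) stop("window error: no frame midpoint inside window")
  }
  den <- mean(reference$activity[sel])
  if (abs(den) < .Machine$double.eps) stop("division error: zero reference activity")
  mean(target$activity[sel]) / den
}

#' Windowed area under a time-activity curve
#'
#' Trapezoidal integral of the TAC over `[t0, t1]` minutes, taking frame
#' midpoints as abscissae and linearly interpolating the curve at the
#' window edges.  Used as the 30-60 min blood-to-CSF exchange index when
#' applied to an eroded lateral-ventricle TAC.
#'
#' @param target a `tac`.
#' @param t0,t1 window in minutes (defaults 30 and 60).
#' @return Integral in activity x min / mL.
#' @export
auc_window <- function(target, t0 = 30, t1 = 60) {
  stopifnot(inherits(target, "tac"))
  sch <- target$schedule
  if (t1 < t0) stop("window error: t1 < t0")
  lo <- min(sch$mid); hi <- max(sch$mid)
  if (t0 < min(sch$start) - 1e-9 || t1 > max(sch$end) + 1e-9)
    stop("window error: window outside schedule")
  if (t1 == t0) return(0)
  # clamp edges to the midpoint range (constant extrapolation at ends)
  tt <- sch$mid; vv <- target$activity
  at <- function(t) stats::approx(tt, vv, pmin(pmax(t, lo), hi), rule = 2)$y
  xs <- sort(unique(c(t0, tt[tt > t0 & tt < t1], t1)))
  ys <- at(xs)
  sum(diff(xs) * (ys[-1] + ys[-length(ys)]) / 2)
}

#' Richardson-Lucy deconvolution of a parametric map
#'
#' Iterative restoration `x <- x * H(y / H(x))` with `H` an isotropic
#' Gaussian blur of the stated FWHM (the PSF is symmetric, so its adjoint
#' is itself).  Non-negativity is preserved by construction and total
#' intensity is conserved for objects away from the volume edge; used for
#' partial-volume correction of DVR maps before reading out small
#' structures such as the choroid plexus.
#'
#' @param map non-negative 3D array (negative voxels are clipped to zero
#'   with a warning).
#' @param voxdim voxel dimensions (mm).
#' @param psf_fwhm point-spread FWHM (mm), > 0.
#' @param n_iter number of iterations (default 10).
#' @return The deconvolved 3D array.
#' @export
rl_deconvolve <- function(map, voxdim = c(2, 2, 2), psf_fwhm = 6, n_iter = 10) {
  stopifnot(length(dim(map)) == 3L)
  if (n_iter <= 0) stop("parameter error: n_iter must be positive")
  if (psf_fwhm <= 0) stop("parameter error: psf_fwhm must be positive")
  if (any(map < 0)) {
    warning("negative input voxels clipped to zero")
    map[map < 0] <- 0
  }
  fwhm_vox <- psf_fwhm / voxdim
  x <- map
  eps <- .Machine$double.eps
  for (i in seq_len(n_iter)) {
    hx <- gaussian_blur3d(x, fwhm_vox)
    ratio <- map / pmax(hx, eps)
    ratio[map == 0] <- 0
    x <- x * gaussian_blur3d(ratio, fwhm_vox)
  }
  x
}

#' Partial-volume-corrected mean within a mask
#'
#' Mean of an (already deconvolved) parametric map inside a mask — the
#' readout used for choroid-plexus DVR after Richardson-Lucy correction.
#'
#' @param map 3D array (e.g. output of [rl_deconvolve()]).
#' @param mask a `region_mask` on the same grid.
#' @return Mean map value within the mask.
#' @export
cp_dvr_pvc <- function(map, mask) {
  stopifnot(length(dim(map)) == 3L, inherits(mask, "region_mask"))
  if (!all(dim(map) == dim(mask$data)))
    stop("geometry error: map and mask grids differ")
  if (!sum(mask$data)) stop("empty-region error: mask contains no voxels")
  mean(map[mask$data])
}
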