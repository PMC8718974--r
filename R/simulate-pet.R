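#' Synthetic reference-region input curve
#'
#' Builds a gamma-variate rise-and-washout curve
#' \eqn{C(t) = A (t/t_p)^\alpha e^{\alpha (1 - t/t_p)}} peaking at
#' `peak_time`, evaluated on a fine grid and averaged within frames.  This
#' stands in for the measured reference-region curve of a dynamic scan:
#' non-negative, a single early peak, monotone washout afterwards.
#'
#' @param schedule a `frame_schedule` covering the acquisition (>= 10
#'   frames expected for kinetic work).
#' @param peak_time time of the activity peak (min).
#' @param amplitude peak activity (kBq/mL).
#' @param shape gamma shape parameter alpha (sharpness of the peak).
#' @param noise_cov fractional Gaussian noise on frame means (0 = clean).
#' @param seed integer seed used for the noise; the curve is
#'   deterministic given the seed.
#' @return A `tac` carrying its noiseless fine-grid curve.
#' @export
make_reference_tac <- function(schedule, peak_time = 5, amplitude = 20,
                               shape = 3, noise_cov = 0, seed = NULL) {
  stopifnot(inherits(schedule, "frame_schedule"))
  if (nrow(schedule) < 2L) stop("invalid schedule: too few frames")
  if (peak_time <= 0) stop("peak_time must be positive")
  t <- fine_grid(schedule)
  v <- amplitude * (t / peak_time)^shape * exp(shape * (1 - t / peak_time))
  act <- frame_average(t, v, schedule)
  if (noise_cov > 0) {
    if (!is.null(seed)) set.seed(seed)
    act <- act + stats::rnorm(length(act), 0, noise_cov * abs(act))
    act <- pmax(act, 0)
  }
  tac(schedule, act, region = "reference", fine = list(t = t, value = v))
}

#' Canonical kinetic class curves for supervised reference extraction
#'
#' Four normalized class time courses on the given schedule, generated
#' from the reference-tissue forward model plus a blood-like early bolus:
#' `blood` (sharp early peak, fast washout), `normal_grey` (the reference
#' kinetic itself), `white` (low delivery), `high_binding` (elevated
#' binding, slow washout).  Each curve is normalized to unit mean so the
#' decomposition coefficients are comparable.
#'
#' @param schedule a `frame_schedule`.
#' @param ref optional reference `tac`; generated if missing.
#' @return A named list of class `tac`s (normalized), with the
#'   `normal_grey` entry present.
#' @export
kinetic_class_curves <- function(schedule, ref = NULL) {
  if (is.null(ref)) ref <- make_reference_tac(schedule)
  norm1 <- function(x) {
    x$activity <- x$activity / mean(x$activity)
    f <- attr(x, "fine")
    if (!is.null(f)) attr(x, "fine") <- NULL
    x
  }
  blood <- make_reference_tac(schedule, peak_time = 1, shape = 2)
  list(
    blood        = norm1(blood),
    normal_grey  = norm1(ref),
    white        = norm1(simulate_srtm_tac(ref, R1 = 0.65, k2 = 0.08, BPnd = 0)),
    high_binding = norm1(simulate_srtm_tac(ref, R1 = 1.0, k2 = 0.1, BPnd = 1.5))
  )
}

#' Simulate a dynamic PET image from per-parcel kinetics
#'
#' Each voxel of a parcel gets the parcel's noiseless reference-tissue
#' forward curve; every frame is then blurred with an isotropic Gaussian
#' point-spread function of the stated FWHM, and proportional Gaussian
#' noise is added.  The result is the standard test-bed for TAC
#' extraction and partial-volume work: ground truth is known per parcel.
#'
#' @param parcels integer 3D array of parcel labels (0 = background).
#' @param kinetics data frame with columns `label`, `R1`, `k2`, `BPnd`
#'   (one row per parcel label present).
#' @param ref reference `tac` driving all parcels.
#' @param voxdim voxel dimensions in mm (length 3).
#' @param psf_fwhm point-spread FWHM in mm (0 = no blur).
#' @param noise_cov fractional voxel noise (0 = clean).
#' @param seed integer seed.
#' @return A `dynamic_image`: list with `data` (4D array x,y,z,frame),
#'   `voxdim`, `schedule`, and `truth` (per-parcel noiseless frame
#'   curves).
#' @export
simulate_dynamic_image <- function(parcels, kinetics, ref, voxdim = c(2, 2, 2),
                                   psf_fwhm = 0, noise_cov = 0, seed = NULL) {
  stopifnot(length(dim(parcels)) == 3L, inherits(ref, "tac"))
  labs <- sort(setdiff(unique(as.vector(parcels)), 0))
  if (!all(labs %in% kinetics$label))
    stop("kinetics must cover every parcel label present")
  sch <- ref$schedule
  nf <- nrow(sch)
  truth <- lapply(labs, function(l) {
    k <- kinetics[kinetics$label == l, ]
    simulate_srtm_tac(ref, k$R1, k$k2, k$BPnd)$activity
  })
  names(truth) <- as.character(labs)
  dims <- dim(parcels)
  img <- array(0, c(dims, nf))
  idx <- match(as.vector(parcels), labs)        # NA for background
  for (f in seq_len(nf)) {
    vals <- vapply(truth, `[`, numeric(1), f)
    frame <- array(ifelse(is.na(idx), 0, vals[idx]), dims)
    if (psf_fwhm > 0)
      frame <- gaussian_blur3d(frame, psf_fwhm / voxdim)
    img[, , , f] <- frame
  }
  if (noise_cov > 0) {
    if (!is.null(seed)) set.seed(seed)
    sd_f <- noise_cov / sqrt(sch$dur / mean(sch$dur))
    for (f in seq_len(nf))
      img[, , , f] <- img[, , , f] +
        stats::rnorm(prod(dims), 0, 1) * (sd_f[f] * abs(img[, , , f]))
  }
  structure(list(data = img, voxdim = voxdim, schedule = sch, truth = truth),
            class = "dynamic_image")
}

#' @export
print.dynamic_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("dynamic_image: %dx%dx%d voxels (%g x %g x %g mm), %d frames\n",
              d[1], d[2], d[3], x$voxdim[1], x$voxdim[2], x$voxdim[3], d[4]))
  invisible(x)
}

# Separable Gaussian blur of a 3D array; the argument is the FWHM in
# voxels per axis.  The kernel is renormalized at the volume boundary
# (division by the blurred unit image), so constants are exact fixed
# points and flux is conserved for objects away from the edges.
gaussian_blur3d <- function(arr, fwhm_vox) {
  if (length(fwhm_vox) == 1L) fwhm_vox <- rep(fwhm_vox, 3L)
  sigma <- fwhm_vox / (2 * sqrt(2 * log(2)))
  out <- arr
  ones <- array(1, dim(arr))
  for (ax in 1:3) {
    s <- sigma[ax]
    if (s < 1e-8) next
    r <- max(1L, ceiling(3 * s))
    k <- stats::dnorm(-r:r, sd = s)
    k <- k / sum(k)
    out <- conv_axis(out, k, ax)
    ones <- conv_axis(ones, k, ax)
  }
  out / ones
}

# 1D convolution of a 3D array along one axis with zero padding.
conv_axis <- function(arr, k, axis) {
  d <- dim(arr)
  r <- (length(k) - 1L) / 2L
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  a <- aperm(arr, perm)
  m <- matrix(a, nrow = dim(a)[1])
  n <- nrow(m)
  res <- matrix(0, n, ncol(m))
  for (j in seq_along(k)) {
    off <- j - r - 1L
    src <- seq_len(n) + off
    ok <- src >= 1L & src <= n
    res[ok, ] <- res[ok, ] + k[j] * m[src[ok], ]
  }
  a <- array(res, dim(a))
  aperm(a, order(perm))
}
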