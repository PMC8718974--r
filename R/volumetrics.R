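#' Binary region mask
#'
#' @param data logical or 0/1 numeric 3D array.
#' @param voxdim voxel dimensions in mm (length 3, strictly positive).
#' @param label region label.
#' @param space space tag, e.g. `"native"` or `"MNI"`.
#' @return An object of class `region_mask`.
#' @export
region_mask <- function(data, voxdim = c(1, 1, 1), label = NA_character_,
                        space = "native") {
  stopifnot(length(dim(data)) == 3L)
  if (any(voxdim <= 0)) stop("voxel dimensions must be strictly positive")
  d <- array(as.logical(data), dim(data))
  if (any(is.na(d))) stop("mask values must be 0/1")
  structure(list(data = d, voxdim = as.numeric(voxdim), label = label,
                 space = space), class = "region_mask")
}

#' @export
print.region_mask <- function(x, ...) {
  cat(sprintf("region_mask [%s, %s]: %d voxels of %s mm, volume %.1f mm^3\n",
              ifelse(is.na(x$label), "unlabelled", x$label), x$space,
              sum(x$data), paste(x$voxdim, collapse = "x"),
              tryCatch(mask_volume(x), error = function(e) NA_real_)))
  invisible(x)
}

#' Volume of a binary mask
#'
#' Volume in mm^3: voxel count times voxel volume.  Additive over
#' disjoint masks by construction.
#'
#' @param mask a `region_mask`.
#' @return Volume in mm^3.
#' @examples
#' m <- region_mask(array(1, c(5, 5, 4)), voxdim = c(2, 2, 2))
#' mask_volume(m)   # 100 voxels * 8 mm^3 = 800
#' @export
mask_volume <- function(mask) {
  stopifnot(inherits(mask, "region_mask"))
  n <- sum(mask$data)
  if (n == 0L) stop("empty-region error: mask contains no voxels")
  n * prod(mask$voxdim)
}

#' Morphological erosion of a binary mask
#'
#' `n_voxels` iterations of erosion with the face-connected (6-neighbour)
#' structuring element: a voxel survives one iteration iff it and all six
#' face neighbours are in the mask (out-of-volume neighbours count as
#' background).  Anti-extensive (result is a subset of the input) and
#' monotone.  Eroding lateral-ventricle masks this way before TAC
#' extraction limits partial-volume contamination from surrounding
#' tissue.
#'
#' @param mask a `region_mask`.
#' @param n_voxels non-negative number of erosion iterations.
#' @return The eroded `region_mask`.
#' @examples
#' cube <- region_mask(array(1, c(10, 10, 10)))
#' sum(erode_mask(cube, 2)$data)   # 6^3 = 216
#' @export
erode_mask <- function(mask, n_voxels) {
  stopifnot(inherits(mask, "region_mask"))
  if (n_voxels < 0) stop("n_voxels must be >= 0")
  m <- mask$data
  n_voxels <- as.integer(n_voxels)
  for (i in seq_len(n_voxels)) {
    m <- m & shift3d(m, 1, 1) & shift3d(m, -1, 1) &
         shift3d(m, 1, 2) & shift3d(m, -1, 2) &
         shift3d(m, 1, 3) & shift3d(m, -1, 3)
    if (!any(m))
      stop(sprintf("empty-after-erosion error: mask '%s' vanished at iteration %d of %d",
                   mask$label, i, n_voxels))
  }
  out <- mask
  out$data <- m
  out
}

# Shift a logical 3D array by one voxel along an axis, padding with FALSE.
shift3d <- function(m, by, axis) {
  d <- dim(m)
  out <- array(FALSE, d)
  src <- dst <- lapply(d, seq_len)
  if (by > 0) { dst[[axis]] <- (1 + by):d[axis]; src[[axis]] <- 1:(d[axis] - by) }
  else        { dst[[axis]] <- 1:(d[axis] + by); src[[axis]] <- (1 - by):d[axis] }
  out[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
  out
}

#' Residualize values on covariates
#'
#' Least-squares residuals of `values` on the covariate columns plus an
#' intercept — the covariate-adjustment primitive behind partial
#' correlations and adjusted group comparisons (e.g. removing
#' intracranial-volume dependence from regional volumes).  With no
#' covariates this is mean-centering.
#'
#' @param values numeric vector.
#' @param covariates numeric matrix/data frame (n x k) or NULL.
#' @return Numeric residual vector, orthogonal to every covariate.
#' @export
residualize <- function(values, covariates = NULL) {
  n <- length(values)
  if (is.null(covariates) || NCOL(covariates) == 0L) return(values - mean(values))
  X <- stats::model.matrix(~ ., data = as.data.frame(covariates))
  if (nrow(X) != n) stop("values and covariates must have equal length")
  if (n < ncol(X) + 2L) stop("need at least 2 more observations than covariates")
  if (qr(X)$rank < ncol(X)) stop("collinearity error: rank-deficient covariate matrix")
  stats::lm.fit(X, values)$residuals
}

#' Read / write region masks as NIfTI
#'
#' @param path NIfTI file path.
#' @param label,space passed to [region_mask()].
#' @return `read_mask` returns a `region_mask`.
#' @export
read_mask <- function(path, label = NA_character_, space = "native") {
  img <- RNifti::readNifti(path)
  region_mask(array(img > 0.5, dim(img)[1:3]),
              voxdim = RNifti::pixdim(img)[1:3], label = label, space = space)
}

#' @rdname read_mask
#' @param mask a `region_mask`.
#' @export
write_mask <- function(mask, path) {
  img <- RNifti::asNifti(array(as.numeric(mask$data), dim(mask$data)))
  RNifti::pixdim(img) <- mask$voxdim
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Volume records for a set of masks
#'
#' One row per mask: label, voxel count, volume (mm^3) and its log10 —
#' regional volumes are log10-transformed before normality-based
#' statistics.
#'
#' @param masks a `region_mask` or list of them.
#' @param subject subject identifier.
#' @param icv intracranial volume (mm^3), carried as covariate.
#' @return A data frame with columns `subject`, `label`, `n_voxels`,
#'   `volume`, `log10_volume`, `icv`.
#' @export
volume_record <- function(masks, subject = NA_character_, icv = NA_real_) {
  if (inherits(masks, "region_mask")) masks <- list(masks)
  do.call(rbind, lapply(masks, function(m) {
    v <- mask_volume(m)
    data.frame(subject = subject, label = m$label, n_voxels = sum(m$data),
               volume = v, log10_volume = log10(v), icv = icv)
  }))
}
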