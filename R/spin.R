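#' Parcellation geometry
#'
#' Per-region centroid coordinates with hemisphere and cortical flags —
#' the substrate of spatial permutation testing.  Cortical centroids are
#' projected onto a sphere around their centroid for spinning.
#'
#' @param region character region labels (unique).
#' @param x,y,z centroid coordinates (mm).
#' @param hemisphere `"L"`/`"R"` per region.
#' @param cortical logical per region; subcortical regions are permuted
#'   freely rather than rotated.
#' @return An object of class `parcellation_geometry` (a data frame).
#' @export
parcellation_geometry <- function(region, x, y, z,
                                  hemisphere = "L", cortical = TRUE) {
  if (anyDuplicated(region)) stop("region labels must be unique")
  out <- data.frame(region = region, x = x, y = y, z = z,
                    hemisphere = hemisphere, cortical = cortical)
  class(out) <- c("parcellation_geometry", "data.frame")
  out
}

#' Read / write parcel centroids as CSV
#'
#' Columns: `region, x, y, z, hemisphere, cortical`.
#'
#' @param path file path.
#' @return `read_geometry` returns a `parcellation_geometry`.
#' @export
read_geometry <- function(path) {
  tab <- utils::read.csv(path)
  parcellation_geometry(tab$region, tab$x, tab$y, tab$z,
                        tab$hemisphere, as.logical(tab$cortical))
}

#' @rdname read_geometry
#' @param geometry a `parcellation_geometry`.
#' @export
write_geometry <- function(geometry, path) {
  utils::write.csv(as.data.frame(geometry), path, row.names = FALSE)
  invisible(path)
}

# Uniform random 3D rotation matrix (QR of a Gaussian matrix, det +1).
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3))
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# One spin permutation: rotate cortical unit-sphere centroids and
# greedily reassign each original region the value of its nearest
# rotated neighbour (without replacement, closest pairs first);
# subcortical values are permuted freely.
spin_permute_once <- function(coords_cort, idx_cort, idx_sub, y) {
  perm <- y
  if (length(idx_cort)) {
    R <- random_rotation()
    rot <- coords_cort %*% t(R)
    D <- as.matrix(stats::dist(rbind(coords_cort, rot)))[
      seq_len(nrow(coords_cort)),
      nrow(coords_cort) + seq_len(nrow(coords_cort)), drop = FALSE]
    assign <- integer(nrow(D))
    free_r <- rep(TRUE, nrow(D)); free_c <- rep(TRUE, ncol(D))
    for (k in seq_len(nrow(D))) {
      Dm <- D
      Dm[!free_r, ] <- Inf; Dm[, !free_c] <- Inf
      ij <- arrayInd(which.min(Dm), dim(D))
      assign[ij[1]] <- ij[2]
      free_r[ij[1]] <- FALSE; free_c[ij[2]] <- FALSE
    }
    perm[idx_cort] <- y[idx_cort][assign]
  }
  if (length(idx_sub) > 1L)
    perm[idx_sub] <- y[idx_sub][sample.int(length(idx_sub))]
  perm
}

#' Spatial spin-test null for a regional statistic
#'
#' Builds a permutation null for any statistic of a regional map that
#' respects spatial autocorrelation: each permutation applies a uniform
#' random 3D rotation to the sphere-projected cortical centroids and
#' reassigns each region the map value of its nearest rotated neighbour
#' (greedy matching without replacement); subcortical regions, which have
#' no spherical embedding, are permuted freely.  The p-value uses the
#' add-one convention `p = (1 + #\{null >= observed\}) / (1 + n_perm)`, so
#' it is never smaller than `1/(1 + n_perm)`.
#'
#' @param geometry a `parcellation_geometry` aligned with `y`.
#' @param y regional map.
#' @param statistic_fn function(y_permuted) -> scalar; the observed value
#'   is `statistic_fn(y)`.
#' @param n_perm number of permutations (default 1000; < 100 warns).
#' @param seed integer seed.
#' @return List: `observed`, `null` (length `n_perm`), `p`.
#' @export
spin_null <- function(geometry, y, statistic_fn, n_perm = 1000, seed = NULL) {
  stopifnot(inherits(geometry, "parcellation_geometry"),
            length(y) == nrow(geometry))
  if (n_perm < 100) warning("n_perm < 100 gives a coarse null")
  if (!is.null(seed)) set.seed(seed)
  idx_cort <- which(geometry$cortical)
  idx_sub <- which(!geometry$cortical)
  if (length(idx_cort) < 3L && length(idx_sub) < 2L)
    stop("degenerate geometry: nothing to permute")
  coords_cort <- NULL
  if (length(idx_cort)) {
    cc <- as.matrix(geometry[idx_cort, c("x", "y", "z")])
    cc <- sweep(cc, 2, colMeans(cc))
    nr <- sqrt(rowSums(cc^2))
    if (any(nr < 1e-9)) stop("degenerate geometry: centroid at sphere centre")
    coords_cort <- cc / nr
  }
  observed <- statistic_fn(y)
  null <- vapply(seq_len(n_perm), function(i) {
    statistic_fn(spin_permute_once(coords_cort, idx_cort, idx_sub, y))
  }, numeric(1))
  list(observed = observed, null = null,
       p = (1 + sum(null >= observed)) / (1 + n_perm))
}

#' Bootstrap null for a regional statistic
#'
#' Companion to [spin_null()] without spatial structure: permutes the
#' whole map freely.  Exposed because either null may be the right
#' reference depending on whether the map's autocorrelation should be
#' preserved.
#'
#' @inheritParams spin_null
#' @return List: `observed`, `null`, `p` (add-one convention).
#' @export
permutation_null <- function(y, statistic_fn, n_perm = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  observed <- statistic_fn(y)
  null <- vapply(seq_len(n_perm), function(i) {
    statistic_fn(y[sample.int(length(y))])
  }, numeric(1))
  list(observed = observed, null = null,
       p = (1 + sum(null >= observed)) / (1 + n_perm))
}
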