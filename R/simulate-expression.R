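#' Synthetic parcellation geometry
#'
#' Cortical centroids spread quasi-uniformly (Fibonacci lattice) over a
#' 70 mm hemisphere shell with mild jitter, plus a handful of deep
#' subcortical centroids near the origin — the geometric substrate the
#' spin test needs.
#'
#' @param n_regions total number of regions.
#' @param n_subcortical how many of them are subcortical (default 6).
#' @param seed integer seed.
#' @return A `parcellation_geometry`.
#' @export
make_parcellation_geometry <- function(n_regions = 34L, n_subcortical = 6L,
                                       seed = 1L) {
  stopifnot(n_subcortical < n_regions)
  set.seed(seed)
  nc <- n_regions - n_subcortical
  i <- seq_len(nc) - 0.5
  phi <- acos(1 - 2 * i / nc)
  theta <- pi * (1 + sqrt(5)) * i
  r <- 70
  xyz <- cbind(r * sin(phi) * cos(theta),
               r * sin(phi) * sin(theta),
               r * cos(phi)) + matrix(stats::rnorm(3 * nc, 0, 2), nc)
  sub <- matrix(stats::rnorm(3 * n_subcortical, 0, 8), n_subcortical)
  parcellation_geometry(
    region = c(sprintf("ctx-%02d", seq_len(nc)),
               sprintf("sub-%02d", seq_len(n_subcortical))),
    x = c(xyz[, 1], sub[, 1]), y = c(xyz[, 2], sub[, 2]),
    z = c(xyz[, 3], sub[, 3]),
    hemisphere = "L",
    cortical = rep(c(TRUE, FALSE), c(nc, n_subcortical)))
}

#' Simulate spatially autocorrelated regional gene expression
#'
#' Background genes are draws from a Gaussian field over the parcel
#' centroids with exponential covariance
#' \eqn{K_{ij} = \exp(-d_{ij} / \ell)} (correlation length
#' `autocorr_length` mm), unit marginal SD.  A planted subset of signal
#' genes additionally loads on the standardized target map `y` with
#' coefficient `beta_signal`.  The identity of the signal genes is
#' returned so recovery can be scored.
#'
#' @param geometry a `parcellation_geometry`.
#' @param y target regional map, length `nrow(geometry)`.
#' @param config a `simulation_config` (uses `n_genes`,
#'   `n_signal_genes`, `autocorr_length`, `beta_signal`, `seed`).
#' @return A regions x genes matrix with region rownames and gene-symbol
#'   colnames, attribute `signal_genes` (character vector).
#' @export
simulate_expression <- function(geometry, y, config = simulation_config()) {
  stopifnot(inherits(geometry, "parcellation_geometry"),
            inherits(config, "simulation_config"))
  n <- nrow(geometry)
  if (length(y) != n) stop("geometry regions must match y")
  if (config$n_signal_genes > config$n_genes)
    stop("config error: n_signal_genes > n_genes")
  set.seed(config$seed + 1L)
  D <- as.matrix(stats::dist(geometry[, c("x", "y", "z")]))
  K <- exp(-D / config$autocorr_length)
  L <- t(chol(K + diag(1e-8, n)))
  X <- L %*% matrix(stats::rnorm(n * config$n_genes), n, config$n_genes)
  genes <- sprintf("gene%05d", seq_len(config$n_genes))
  dimnames(X) <- list(geometry$region, genes)
  signal <- sort(sample.int(config$n_genes, config$n_signal_genes))
  ys <- as.numeric(scale(y))
  X[, signal] <- X[, signal] + config$beta_signal * ys
  attr(X, "signal_genes") <- genes[signal]
  X
}

#' Build gene sets around a planted signal
#'
#' One "true" set made of the signal genes (padded with random background
#' genes if smaller than `set_size`), the remaining sets random draws —
#' the fixture for enrichment recovery and calibration.
#'
#' @param genes all gene symbols.
#' @param signal_genes the planted subset (may be empty for null sets).
#' @param n_sets total number of sets (>= 1).
#' @param set_size members per set (<= number of genes).
#' @param seed integer seed.
#' @return Named list of gene sets; the first is `"signal_set"` when
#'   `signal_genes` is non-empty.
#' @export
make_gene_sets <- function(genes, signal_genes = character(), n_sets = 10L,
                           set_size = 40L, seed = 1L) {
  if (set_size > length(genes)) stop("set_size exceeds the number of genes")
  set.seed(seed)
  sets <- list()
  if (length(signal_genes)) {
    true_set <- signal_genes
    if (length(true_set) < set_size)
      true_set <- c(true_set,
                    sample(setdiff(genes, signal_genes),
                           set_size - length(true_set)))
    sets$signal_set <- sort(true_set[seq_len(min(length(true_set), set_size))])
  }
  n_rand <- n_sets - length(sets)
  for (i in seq_len(n_rand))
    sets[[sprintf("random_set_%02d", i)]] <- sort(sample(genes, set_size))
  if (anyDuplicated(names(sets))) stop("format error: duplicate set names")
  sets
}

#' Read / write an expression matrix as CSV
#'
#' Rows are regions (first column `region`), remaining columns gene
#' symbols.
#'
#' @param path file path.
#' @return `read_expression` returns a regions x genes matrix.
#' @export
read_expression <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  m
}

#' @rdname read_expression
#' @param X regions x genes matrix with dimnames.
#' @export
write_expression <- function(X, path) {
  utils::write.csv(data.frame(region = rownames(X), X, check.names = FALSE),
                   path, row.names = FALSE)
  invisible(path)
}
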