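# Shared fixtures, built in code at test time.

fix_schedule <- function() default_schedule()

fix_ref <- function(peak = 5) make_reference_tac(fix_schedule(), peak_time = peak)

# Two-level interior phantom: warm block with a hot core, surrounded by a
# zero margin so blurring loses no mass at the volume edge.
fix_phantom <- function(dims = c(30, 30, 30)) {
  tr <- array(0, dims)
  tr[9:22, 9:22, 9:22] <- 0.3
  tr[14:17, 14:17, 14:17] <- 1.5
  tr
}

# Random blob mask: union of a few dilated seed points on a small grid.
fix_random_mask <- function(dims = c(12, 12, 12), n_seeds = 6) {
  m <- array(FALSE, dims)
  idx <- cbind(sample(3:(dims[1] - 2), n_seeds, TRUE),
               sample(3:(dims[2] - 2), n_seeds, TRUE),
               sample(3:(dims[3] - 2), n_seeds, TRUE))
  for (i in seq_len(n_seeds)) {
    r <- sample(1:2, 1)
    m[max(1, idx[i, 1] - r):min(dims[1], idx[i, 1] + r),
      max(1, idx[i, 2] - r):min(dims[2], idx[i, 2] + r),
      max(1, idx[i, 3] - r):min(dims[3], idx[i, 3] + r)] <- TRUE
  }
  region_mask(m)
}

# Independent brute-force erosion: a voxel survives one 6-connected
# erosion iff itself and all six face neighbours are inside.
brute_erode_once <- function(m) {
  d <- dim(m)
  out <- array(FALSE, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!m[i, j, k]) next
    nb <- rbind(c(i - 1, j, k), c(i + 1, j, k), c(i, j - 1, k),
                c(i, j + 1, k), c(i, j, k - 1), c(i, j, k + 1))
    ok <- all(apply(nb, 1, function(v) {
      all(v >= 1) && all(v <= d) && m[v[1], v[2], v[3]]
    }))
    out[i, j, k] <- ok
  }
  out
}

# Independent brute-force running-sum enrichment score (naive loop).
brute_es <- function(scores, in_set, p = 1) {
  N <- length(scores)
  Nh <- sum(in_set)
  NR <- sum(abs(scores[in_set])^p)
  rs <- 0
  best <- 0
  for (i in seq_len(N)) {
    rs <- rs + if (in_set[i]) abs(scores[i])^p / NR else -1 / (N - Nh)
    if (abs(rs) > abs(best)) best <- rs
  }
  best
}

# Smooth target map over a geometry (exponential-kernel field draw).
fix_smooth_map <- function(geom, length_mm = 20) {
  D <- as.matrix(stats::dist(geom[, c("x", "y", "z")]))
  L <- t(chol(exp(-D / length_mm) + diag(1e-8, nrow(geom))))
  as.numeric(L %*% stats::rnorm(nrow(geom)))
}
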