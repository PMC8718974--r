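#' Bootstrap Z-scored gene ranking from PLS1 weights
#'
#' Quantifies the stability of each gene's first-component PLS weight by
#' bootstrapping regions: for each replicate, regions are resampled with
#' replacement, PLS1 refit, and the replicate weight vector's sign
#' aligned to the original by the sign of their dot product (PLS weights
#' are sign-indeterminate).  The per-gene bootstrap SD is the standard
#' error; `Z = weight / SE` ranks genes by their contribution to the
#' component.  Replicates with fewer than 3 distinct regions are redrawn.
#'
#' @param X regions x genes expression matrix.
#' @param y regional map.
#' @param n_boot bootstrap replicates (>= 100).
#' @param seed integer seed.
#' @return An object of class `gene_ranking`: data frame with columns
#'   `gene`, `weight`, `se`, `z`, `rank`, ordered by `z` descending.
#' @export
bootstrap_gene_z <- function(X, y, n_boot = 1000, seed = NULL) {
  X <- as.matrix(X)
  if (n_boot < 100) stop("n_boot must be >= 100")
  if (!is.null(seed)) set.seed(seed)
  fit <- pls_fit(X, y, n_components = 1)
  w0 <- fit$weights[, 1]
  n <- nrow(X)
  boot <- matrix(NA_real_, length(w0), n_boot)
  redraws <- 0L
  for (b in seq_len(n_boot)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(idx)) >= 3L && stats::sd(y[idx]) > 0 &&
          all(apply(X[idx, , drop = FALSE], 2, stats::sd) > 0)) break
      redraws <- redraws + 1L
    }
    wb <- pls_fit(X[idx, , drop = FALSE], y[idx], n_components = 1)$weights[, 1]
    if (sum(wb * w0) < 0) wb <- -wb
    boot[, b] <- wb
  }
  se <- apply(boot, 1, stats::sd)
  z <- w0 / pmax(se, .Machine$double.eps)
  out <- data.frame(gene = names(w0), weight = unname(w0),
                    se = se, z = unname(z))
  out <- out[order(-out$z), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  structure(out, class = c("gene_ranking", "data.frame"),
            n_boot = n_boot, redraws = redraws)
}

#' @export
print.gene_ranking <- function(x, n = 6, ...) {
  cat(sprintf("gene_ranking: %d genes, %d bootstrap replicates\n",
              nrow(x), attr(x, "n_boot")))
  print.data.frame(utils::head(x, n))
  invisible(x)
}

#' Write a gene ranking as TSV
#'
#' @param ranking a `gene_ranking`.
#' @param path file path.
#' @export
write_ranking <- function(ranking, path) {
  utils::write.table(as.data.frame(ranking), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
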