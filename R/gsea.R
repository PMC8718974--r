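#' Read / write gene sets in GMT format
#'
#' Reading goes through the standard GMT parser; writing emits the usual
#' `name<TAB>description<TAB>gene...` lines.
#'
#' @param path file path.
#' @return `read_gmt` returns a named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' @rdname read_gmt
#' @param sets named list of character vectors of gene symbols.
#' @export
write_gmt <- function(sets, path) {
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("format error: gene set names must be present and unique")
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# Weighted running-sum enrichment score of one set within a ranked,
# scored gene list (genes ordered by decreasing score).  Returns the
# signed maximum deviation and the index attaining it.
running_es <- function(scores, in_set, weight_p = 1) {
  N <- length(scores)
  Nh <- sum(in_set)
  if (Nh == 0L || Nh == N) stop("set must be a proper subset of the ranking")
  w <- abs(scores)^weight_p
  NR <- sum(w[in_set])
  step <- ifelse(in_set, if (NR > 0) w / NR else 1 / Nh, -1 / (N - Nh))
  if (NR == 0) step[in_set] <- 1 / Nh
  rs <- cumsum(step)
  i <- which.max(abs(rs))
  list(es = rs[i], at = i, running = rs)
}

#' Pre-ranked gene set enrichment analysis
#'
#' Local implementation of pre-ranked GSEA over a bootstrap Z-ranked gene
#' list: for each set, a running sum over the ranking increments by
#' `|Z|^weight_p` (normalized) at members and decrements uniformly at
#' non-members; the enrichment score ES is the signed maximum deviation.
#' The null distribution permutes gene labels (`n_perm` random sets of
#' the same size); NES divides ES by the mean |null ES| of the same sign,
#' the nominal p uses the add-one same-sign tail, and FDR is
#' Benjamini-Hochberg across the tested sets.  Set members missing from
#' the ranking are dropped with a warning; sets with fewer than
#' `min_size` effective members are skipped.
#'
#' @param ranking a `gene_ranking` (or data frame with `gene` and `z`).
#' @param sets named list of gene-symbol vectors.
#' @param weight_p running-sum weight exponent (default 1).
#' @param n_perm label permutations (default 1000).
#' @param min_size minimum effective set size (default 5).
#' @param seed integer seed.
#' @return An `enrichment_result` data frame: `set`, `size`, `es`, `nes`,
#'   `p`, `fdr`, `leading_edge` (semicolon-joined symbols).
#' @export
gsea_preranked <- function(ranking, sets, weight_p = 1, n_perm = 1000,
                           min_size = 5, seed = NULL) {
  stopifnot(is.data.frame(ranking), all(c("gene", "z") %in% names(ranking)))
  ord <- order(-ranking$z)
  genes <- ranking$gene[ord]
  scores <- ranking$z[ord]
  N <- length(genes)
  if (!is.null(seed)) set.seed(seed)

  rows <- list()
  for (nm in names(sets)) {
    members <- unique(sets[[nm]])
    absent <- setdiff(members, genes)
    if (length(absent))
      warning(sprintf("set '%s': %d member(s) absent from ranking dropped",
                      nm, length(absent)))
    members <- intersect(members, genes)
    if (length(members) < min_size) {
      warning(sprintf("set '%s' skipped: effective size %d < %d",
                      nm, length(members), min_size))
      next
    }
    in_set <- genes %in% members
    obs <- running_es(scores, in_set, weight_p)
    null_es <- vapply(seq_len(n_perm), function(i) {
      running_es(scores, seq_len(N) %in% sample.int(N, sum(in_set)),
                 weight_p)$es
    }, numeric(1))
    same <- null_es[sign(null_es) == sign(obs$es)]
    nes <- if (length(same)) obs$es / mean(abs(same)) else NA_real_
    p <- (1 + sum(abs(same) >= abs(obs$es))) / (1 + length(same))
    le <- if (obs$es >= 0) genes[seq_len(obs$at)][in_set[seq_len(obs$at)]]
          else genes[obs$at:N][in_set[obs$at:N]]
    rows[[nm]] <- data.frame(set = nm, size = sum(in_set), es = obs$es,
                             nes = nes, p = p,
                             leading_edge = paste(le, collapse = ";"))
  }
  if (!length(rows)) stop("no gene set passed the size filter")
  out <- do.call(rbind, rows)
  out$fdr <- adjust_pvalues(out$p, "BH")
  out <- out[order(-out$nes), c("set", "size", "es", "nes", "p", "fdr",
                                "leading_edge")]
  rownames(out) <- NULL
  structure(out, class = c("enrichment_result", "data.frame"))
}

#' @export
print.enrichment_result <- function(x, ...) {
  df <- as.data.frame(x)
  df$leading_edge <- NULL
  print.data.frame(df, digits = 3)
  invisible(x)
}

#' Brain cell-type enrichment
#'
#' Runs pre-ranked GSEA with one gene set per cell class and flags
#' classes whose enrichment does not survive FDR < `alpha`; non-surviving
#' classes are reported but marked `significant = FALSE` (the "white
#' squares" of a cell-class enrichment panel).
#'
#' @param ranking a `gene_ranking`.
#' @param cell_class_sets named list, one gene set per cell class.
#' @param alpha FDR threshold (default 0.05).
#' @param ... passed to [gsea_preranked()].
#' @return An `enrichment_result` with an extra `significant` column.
#' @export
cell_type_enrichment <- function(ranking, cell_class_sets, alpha = 0.05, ...) {
  res <- gsea_preranked(ranking, cell_class_sets, ...)
  res$significant <- res$fdr < alpha
  res
}
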