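#' Partial least squares of a regional map on gene expression
#'
#' Fits PLS regression of a univariate regional statistic map `y` on a
#' regions x genes expression matrix by NIPALS with deflation.  Gene
#' columns are z-scored and `y` centred before fitting, so the first
#' component's weight vector is the unit vector maximising the covariance
#' between the projected expression and the map.  The fraction of
#' variance in `y` explained by each successive component is reported;
#' with orthogonal scores these fractions add.
#'
#' @param X numeric matrix, regions x genes, with gene symbols as column
#'   names; no missing values; at least 10 regions.
#' @param y numeric regional map, length `nrow(X)`.
#' @param n_components number of components (capped at 15 and at the
#'   problem rank).
#' @param scale z-score the gene columns (default TRUE).
#' @return An object of class `pls_fit`: `weights` (genes x components,
#'   unit columns), `scores`, `loadings`, `yloadings`, `varexp`
#'   (per-component fraction of y variance), `y`, `X` dims and scaling.
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(30 * 50), 30, 50, dimnames = list(NULL, paste0("g", 1:50)))
#' y <- X[, 1] + rnorm(30, 0, 0.1)
#' f <- pls_fit(X, y)
#' names(which.max(abs(f$weights[, 1])))
#' @export
pls_fit <- function(X, y, n_components = 8, scale = TRUE) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(length(y) == n)
  if (any(!is.finite(X)) || any(!is.finite(y))) stop("missing/non-finite values")
  if (stats::sd(y) == 0) stop("degenerate-response error: constant y")
  if (is.null(colnames(X))) colnames(X) <- paste0("g", seq_len(ncol(X)))
  n_components <- min(n_components, 15L, n - 1L, ncol(X))

  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  if (scale && any(sdv == 0)) stop("constant gene column cannot be z-scored")
  Xc <- sweep(X, 2, mu)
  if (scale) Xc <- sweep(Xc, 2, sdv, "/")
  yc <- y - mean(y)
  ssy <- sum(yc^2)

  p <- ncol(X)
  W <- matrix(0, p, n_components, dimnames = list(colnames(X), NULL))
  P <- matrix(0, p, n_components)
  Tm <- matrix(0, n, n_components)
  q <- numeric(n_components)
  varexp <- numeric(n_components)
  Xd <- Xc; yd <- yc
  a <- 0L
  for (comp in seq_len(n_components)) {
    wv <- crossprod(Xd, yd)[, 1]
    nw <- sqrt(sum(wv^2))
    if (nw < 1e-12) break
    wv <- wv / nw
    tv <- Xd %*% wv
    tt <- sum(tv^2)
    if (tt < 1e-12) break
    pv <- crossprod(Xd, tv)[, 1] / tt
    qv <- sum(yd * tv) / tt
    Xd <- Xd - tv %*% t(pv)
    yd <- yd - qv * tv
    a <- comp
    W[, a] <- wv; P[, a] <- pv; Tm[, a] <- tv; q[a] <- qv
    varexp[a] <- qv^2 * tt / ssy
  }
  if (a == 0L) stop("no usable PLS component (X'y numerically zero)")
  keep <- seq_len(a)
  structure(list(weights = W[, keep, drop = FALSE],
                 loadings = P[, keep, drop = FALSE],
                 scores = Tm[, keep, drop = FALSE],
                 yloadings = q[keep], varexp = varexp[keep],
                 y = y, center = mu, scale = if (scale) sdv else NULL,
                 n_regions = n, n_genes = p),
            class = "pls_fit")
}

#' @export
print.pls_fit <- function(x, ...) {
  cat(sprintf("PLS fit: %d regions x %d genes, %d component(s)\n",
              x$n_regions, x$n_genes, ncol(x$weights)))
  cat("  variance in map explained per component:",
      paste(sprintf("%.1f%%", 100 * x$varexp), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.pls_fit <- function(object, ...) {
  data.frame(component = seq_along(object$varexp),
             varexp = object$varexp,
             cumulative = cumsum(object$varexp))
}

#' @export
coef.pls_fit <- function(object, component = 1, ...) {
  object$weights[, component]
}

#' @export
predict.pls_fit <- function(object, newdata = NULL, n_components = NULL, ...) {
  k <- n_components %||% ncol(object$weights)
  if (is.null(newdata)) {
    return(mean(object$y) +
             object$scores[, seq_len(k), drop = FALSE] %*% object$yloadings[seq_len(k)])
  }
  Xc <- sweep(as.matrix(newdata), 2, object$center)
  if (!is.null(object$scale)) Xc <- sweep(Xc, 2, object$scale, "/")
  # regression coefficients b = W (P'W)^-1 q
  W <- object$weights[, seq_len(k), drop = FALSE]
  P <- object$loadings[, seq_len(k), drop = FALSE]
  b <- W %*% solve(crossprod(P, W), object$yloadings[seq_len(k)])
  mean(object$y) + Xc %*% b
}

#' Fraction of map variance explained by the first PLS component
#'
#' Closed form for the first component: with z-scored gene columns
#' `Xs` and centred map `yc`, the PLS1 score is `t = Xs Xs' yc` and the
#' explained fraction `(yc't)^2 / (t't yc'yc)` — the squared correlation
#' between the map and its first-component projection.  Agrees with
#' `pls_fit(X, y)$varexp[1]` but is cheap enough for permutation loops;
#' pass a pre-standardized matrix with `scale = FALSE` to amortise the
#' column scaling across permutations.
#'
#' @param X regions x genes matrix.
#' @param y regional map.
#' @param scale z-score the gene columns first (default TRUE).
#' @return Scalar in [0, 1].
#' @export
pls1_varexp <- function(X, y, scale = TRUE) {
  Xs <- if (scale) base::scale(X) else X
  yc <- y - mean(y)
  tv <- Xs %*% crossprod(Xs, yc)
  sum(yc * tv)^2 / (sum(tv^2) * sum(yc^2))
}
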