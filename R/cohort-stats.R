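#' Pooled two-sample t-test from raw data or printed summaries
#'
#' Student's pooled-variance t with df = n1 + n2 - 2.  Accepts either two
#' raw vectors or two summary lists `list(n=, mean=, sd=)` — published
#' cohort tables print only summaries, and the pooled t is exactly
#' recomputable from them.  Welch's unequal-variance form is available
#' for raw or summary input via `variant = "welch"`.
#'
#' @param a,b numeric vectors, or lists with elements `n`, `mean`, `sd`.
#' @param variant `"pooled"` (default) or `"welch"`.
#' @return A `test_result` list: `statistic`, `df`, `p`, `estimate`
#'   (mean difference a - b), `method`.
#' @examples
#' two_sample_t(list(n = 51, mean = 2.9, sd = 2.8),
#'              list(n = 25, mean = 1.1, sd = 0.9))$statistic  # ~3.13
#' @export
two_sample_t <- function(a, b, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  s <- function(x) {
    if (is.list(x)) {
      stopifnot(all(c("n", "mean", "sd") %in% names(x)))
      x
    } else list(n = length(x), mean = mean(x), sd = stats::sd(x))
  }
  sa <- s(a); sb <- s(b)
  if (sa$n < 2 || sb$n < 2) stop("need n >= 2 per group")
  if (sa$sd <= 0 && sb$sd <= 0) stop("degenerate error: zero variance in both groups")
  diff <- sa$mean - sb$mean
  if (variant == "pooled") {
    df <- sa$n + sb$n - 2
    sp2 <- ((sa$n - 1) * sa$sd^2 + (sb$n - 1) * sb$sd^2) / df
    se <- sqrt(sp2 * (1 / sa$n + 1 / sb$n))
  } else {
    v1 <- sa$sd^2 / sa$n; v2 <- sb$sd^2 / sb$n
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (sa$n - 1) + v2^2 / (sb$n - 1))
  }
  t <- diff / se
  test_result(statistic = t, df = df, p = 2 * stats::pt(-abs(t), df),
              estimate = diff, method = paste0(variant, " two-sample t"))
}

#' Shapiro-Wilk normality test
#'
#' Thin wrapper over the standard Royston-approximation implementation,
#' with the degenerate-input contract made explicit.
#'
#' @param values numeric vector, 3 <= n <= 5000.
#' @return A `test_result` with `statistic` = W.
#' @export
shapiro_wilk <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 3 || length(values) > 5000)
    stop("need 3 <= n <= 5000 finite values")
  if (stats::sd(values) == 0) stop("degenerate error: constant vector")
  sw <- stats::shapiro.test(values)
  test_result(statistic = unname(sw$statistic), df = length(values),
              p = sw$p.value, estimate = NA_real_, method = "Shapiro-Wilk W")
}

#' Partial correlation with covariate adjustment
#'
#' Pearson correlation of the two covariate-residualized vectors, with
#' df = n - 2 - k and the two-sided p from t = r sqrt(df / (1 - r^2)).
#' With no covariates this reduces to the plain Pearson correlation.
#'
#' @param x,y numeric vectors.
#' @param covariates numeric matrix/data frame or NULL.
#' @return A `test_result` with `statistic` = r.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  n <- length(x)
  stopifnot(length(y) == n)
  k <- if (is.null(covariates)) 0L else NCOL(covariates)
  if (n <= k + 3L) stop("need n > k + 3 observations")
  rx <- residualize(x, covariates)
  ry <- residualize(y, covariates)
  # a variable fully explained by the covariates has nothing left to
  # correlate: report r = 0 rather than noise from ~zero residuals
  if (stats::sd(rx) < 1e-10 * max(stats::sd(x), 1) ||
      stats::sd(ry) < 1e-10 * max(stats::sd(y), 1)) {
    r <- 0
  } else {
    r <- stats::cor(rx, ry)
  }
  df <- n - 2L - k
  tval <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  test_result(statistic = r, df = df, p = 2 * stats::pt(-abs(tval), df),
              estimate = r, method = sprintf("partial correlation (k = %d)", k))
}

#' ANCOVA group effect
#'
#' F statistic for the group factor in `y ~ group + covariates`, i.e. the
#' partial (Type-III) F for group after the covariates — the adjusted
#' group comparison used once head-size or other confounds must be held
#' fixed.  With no covariates this F is exactly the square of the pooled
#' two-sample t.
#'
#' @param y numeric response.
#' @param group factor-like with exactly 2+ levels, both represented.
#' @param covariates numeric matrix/data frame or NULL.
#' @return A `test_result` with `statistic` = F and `df` = c(df1, df2).
#' @export
ancova_group_effect <- function(y, group, covariates = NULL) {
  group <- droplevels(as.factor(group))
  if (nlevels(group) < 2L) stop("design error: need both groups represented")
  if (stats::sd(y) == 0) stop("degenerate error: constant response")
  dat <- data.frame(y = y, group = group)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    names(covariates) <- make.names(names(covariates), unique = TRUE)
    dat <- cbind(dat, covariates)
  }
  rhs <- setdiff(names(dat), "y")
  full <- stats::lm(stats::reformulate(rhs, "y"), data = dat)
  red <- stats::lm(stats::reformulate(setdiff(rhs, "group") %||% "1", "y"),
                   data = dat)
  cmp <- stats::anova(red, full)
  gcoef <- stats::coef(full)[grep("^group", names(stats::coef(full)))][1]
  test_result(statistic = cmp$F[2], df = c(cmp$Df[2], cmp$Res.Df[2]),
              p = cmp$`Pr(>F)`[2], estimate = unname(gcoef),
              method = "ANCOVA group F")
}

`%||%` <- function(a, b) if (length(a)) a else b

#' Multiple-comparison adjustment
#'
#' Bonferroni or Benjamini-Hochberg adjusted p-values, capped at 1.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @param method `"BH"` (default) or `"bonferroni"`.
#' @return Adjusted p-values.
#' @export
adjust_pvalues <- function(p, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("input error: p outside [0, 1]")
  stats::p.adjust(p, method = method)
}

test_result <- function(statistic, df, p, estimate, method) {
  structure(list(statistic = statistic, df = df, p = p,
                 estimate = estimate, method = method),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, df = %s, p = %.4g\n",
              x$method, x$statistic, paste(round(x$df, 2), collapse = ", "), x$p))
  invisible(x)
}

#' Read / write a cohort table as TSV
#'
#' @param path file path.
#' @return `read_cohort` returns a data frame with `group` as factor.
#' @export
read_cohort <- function(path) {
  tab <- utils::read.delim(path, sep = "\t")
  if ("group" %in% names(tab)) tab$group <- factor(tab$group)
  tab
}

#' @rdname read_cohort
#' @param table cohort data frame.
#' @export
write_cohort <- function(table, path) {
  utils::write.table(table, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
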