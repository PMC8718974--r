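test_that("pooled t from raw data equals pooled t from its own summaries", {
  set.seed(3)
  a <- rnorm(40, 1, 2); b <- rnorm(25, 0.2, 1.5)
  raw <- two_sample_t(a, b)
  summ <- two_sample_t(list(n = 40, mean = mean(a), sd = sd(a)),
                       list(n = 25, mean = mean(b), sd = sd(b)))
  expect_equal(raw$statistic, summ$statistic, tolerance = 1e-12)
  expect_equal(raw$p, summ$p, tolerance = 1e-12)
  expect_equal(raw$df, 63)

  same <- two_sample_t(a, a)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  expect_error(two_sample_t(rep(1, 5), rep(1, 5)), "degenerate")

  # base t.test as an independent cross-check of both variants
  expect_equal(raw$statistic, unname(t.test(a, b, var.equal = TRUE)$statistic),
               tolerance = 1e-12)
  w <- two_sample_t(a, b, variant = "welch")
  expect_equal(w$statistic, unname(t.test(a, b)$statistic), tolerance = 1e-12)
  expect_equal(w$df, unname(t.test(a, b)$parameter), tolerance = 1e-9)
})

test_that("Shapiro-Wilk wrapper: calibration on Gaussian samples, power on exponential", {
  ps <- vapply(1:100, function(s) {
    set.seed(s)
    shapiro_wilk(rnorm(500))$p
  }, numeric(1))
  expect_gte(mean(ps > 0.05), 0.90)

  set.seed(1)
  expect_lt(shapiro_wilk(rexp(100))$p, 0.01)

  sw <- shapiro_wilk(qnorm(ppoints(50)))
  expect_gte(sw$statistic, 0.99)
  expect_error(shapiro_wilk(rep(2, 10)), "degenerate")
})

test_that("partial correlation: reduction to Pearson, covariate removal, symmetry, affine invariance", {
  set.seed(21)
  x <- rnorm(40); y <- 0.5 * x + rnorm(40); z <- rnorm(40)
  p0 <- partial_correlation(x, y)
  expect_equal(p0$statistic, cor(x, y), tolerance = 1e-12)
  expect_equal(p0$p, cor.test(x, y)$p.value, tolerance = 1e-10)

  pz <- partial_correlation(x, z, covariates = cbind(z))
  expect_lt(abs(pz$statistic), 1e-10)

  pa <- partial_correlation(x, y, cbind(z))
  pb <- partial_correlation(y, x, cbind(z))
  expect_equal(pa$statistic, pb$statistic, tolerance = 1e-12)
  pc <- partial_correlation(3 * x - 1, -2 * y + 5, cbind(10 * z + 2))
  expect_equal(abs(pc$statistic), abs(pa$statistic), tolerance = 1e-12)
  expect_equal(pa$df, 40 - 2 - 1)
})

test_that("cohort generator plants a recoverable partial correlation at the study's n", {
  ests <- vapply(1:500, function(s) {
    sim <- simulate_cohort(simulation_config(seed = s))
    tab <- sim$table
    partial_correlation(tab$log10_cp_volume, tab$dvr_CP,
                        cbind(tab$icv, as.numeric(tab$group)))$statistic
  }, numeric(1))
  expect_lt(abs(mean(ests) - 0.34), 0.03)

  big <- simulate_cohort(simulation_config(seed = 9, n_depressed = 500,
                                           n_control = 250,
                                           partial_r_cp_dvr = 0.5))
  tab <- big$table
  est <- partial_correlation(tab$log10_cp_volume, tab$dvr_CP,
                             cbind(tab$icv, as.numeric(tab$group)))$statistic
  expect_lt(abs(est - 0.5), 0.07)

  a <- simulate_cohort(simulation_config(seed = 5))
  b <- simulate_cohort(simulation_config(seed = 5))
  expect_identical(a$table, b$table)
})

test_that("under a null configuration the group t-test has calibrated type-I error", {
  rej <- vapply(1:500, function(s) {
    sim <- simulate_cohort(simulation_config(
      seed = 10000 + s, n_depressed = 200, n_control = 200,
      cp_volume_effect = 0, partial_r_cp_dvr = 0))
    tab <- sim$table
    two_sample_t(tab$log10_cp_volume[tab$group == "depressed"],
                 tab$log10_cp_volume[tab$group == "control"])$p < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})

test_that("ANCOVA group F reduces to t-squared without covariates and calibrates under permutation", {
  sim <- simulate_cohort(simulation_config(seed = 2, cp_volume_effect = 0.8))
  tab <- sim$table
  an <- ancova_group_effect(tab$log10_cp_volume, tab$group)
  tt <- two_sample_t(tab$log10_cp_volume[tab$group == "depressed"],
                     tab$log10_cp_volume[tab$group == "control"])
  expect_equal(an$statistic, tt$statistic^2, tolerance = 1e-9)

  an2 <- ancova_group_effect(tab$log10_cp_volume, tab$group,
                             covariates = data.frame(icv = tab$icv))
  expect_true(is.finite(an2$statistic) && an2$df[1] == 1)

  set.seed(31)
  y <- tab$log10_cp_volume
  ps <- vapply(1:500, function(i) {
    ancova_group_effect(y, sample(tab$group),
                        covariates = data.frame(icv = tab$icv))$p
  }, numeric(1))
  expect_gte(mean(ps < 0.05), 0.03)
  expect_lte(mean(ps < 0.05), 0.07)

  expect_error(ancova_group_effect(y, rep("depressed", length(y))), "design error")
  expect_error(ancova_group_effect(rep(1, nrow(tab)), tab$group), "degenerate")
})

test_that("p-value adjustment matches the brute-force step-up definition", {
  expect_equal(adjust_pvalues(0.01, "bonferroni"), 0.01)
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03), "bonferroni"),
               c(0.03, 0.06, 0.09))
  set.seed(41)
  p <- runif(25)
  # independent BH step-up: q_i = min_{j >= i} p_(j) m / j
  o <- order(p)
  m <- length(p)
  q_sorted <- rev(cummin(rev(sort(p) * m / seq_len(m))))
  brute <- numeric(m); brute[o] <- pmin(q_sorted, 1)
  expect_equal(adjust_pvalues(p, "BH"), brute, tolerance = 1e-12)
  expect_error(adjust_pvalues(c(0.5, 1.2)), "input error")
})

test_that("cohort tables round-trip through TSV", {
  sim <- simulate_cohort(simulation_config(seed = 3, n_depressed = 8, n_control = 5))
  f <- tempfile(fileext = ".tsv")
  write_cohort(sim$table, f)
  back <- read_cohort(f)
  expect_equal(back$cp_volume, sim$table$cp_volume, tolerance = 1e-8)
  expect_equal(levels(back$group), levels(sim$table$group))
})
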