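test_that("PLS matches an independent implementation and honours its invariances", {
  skip_if_not_installed("mixOmics")
  set.seed(12)
  X <- matrix(rnorm(10 * 50), 10, 50, dimnames = list(NULL, sprintf("g%02d", 1:50)))
  y <- rnorm(10)
  f <- pls_fit(X, y, n_components = 3)
  m <- mixOmics::pls(X, y, ncomp = 3, mode = "regression", scale = TRUE)
  # variance explained via incremental R^2 on the oracle's scores
  r2 <- vapply(1:3, function(k) {
    summary(stats::lm(y ~ m$variates$X[, 1:k]))$r.squared
  }, numeric(1))
  expect_equal(cumsum(f$varexp), r2, tolerance = 1e-8)
  expect_lt(max(abs(abs(f$weights[, 1]) - abs(m$loadings$X[, 1]))), 1e-8)

  # gene column permutation leaves varexp unchanged; y sign flip flips weights
  perm <- sample(ncol(X))
  expect_equal(pls_fit(X[, perm], y, 3)$varexp, f$varexp, tolerance = 1e-10)
  fneg <- pls_fit(X, -y, 3)
  expect_equal(fneg$varexp, f$varexp, tolerance = 1e-10)
  expect_equal(fneg$weights[, 1], -f$weights[, 1], tolerance = 1e-10)
})

test_that("PLS degenerate and limiting cases: single dominating gene and the OLS limit", {
  set.seed(13)
  X <- matrix(rnorm(30 * 20), 30, 20, dimnames = list(NULL, sprintf("g%02d", 1:20)))
  y <- as.numeric(scale(X[, 7]))
  f <- pls_fit(X, y, n_components = 1)
  expect_equal(names(which.max(abs(f$weights[, 1]))), "g07")

  exact <- pls_fit(X[, 1:6], X[, 7] * 2 + 1e-8 * rnorm(30), n_components = 1)
  expect_true(all(exact$varexp <= 1 + 1e-12))

  # full-rank cumulative variance explained equals the OLS R^2
  Xs <- X[1:15, 1:6]
  ys <- rnorm(15)
  full <- pls_fit(Xs, ys, n_components = 6)
  expect_equal(sum(full$varexp), summary(stats::lm(ys ~ Xs))$r.squared,
               tolerance = 1e-8)

  expect_error(pls_fit(X, rep(1, 30)), "degenerate-response")
  expect_equal(pls1_varexp(X, y), pls_fit(X, y, 1)$varexp[1], tolerance = 1e-12)
})

test_that("spin permutations preserve the cortical value multiset and the add-one floor", {
  geom <- make_parcellation_geometry(30, 5, seed = 2)
  set.seed(2)
  y <- rnorm(30)
  seen <- spin_null(geom, y, statistic_fn = function(yy) {
    expect_equal(sort(yy[geom$cortical]), sort(y[geom$cortical]))
    expect_equal(sort(yy[!geom$cortical]), sort(y[!geom$cortical]))
    mean(yy)
  }, n_perm = 100, seed = 5)
  expect_gte(seen$p, 1 / 101)
  expect_lte(seen$p, 1)
  expect_length(seen$null, 100)
  expect_warning(spin_null(geom, y, mean, n_perm = 50, seed = 1), "coarse")
})

test_that("bootstrap gene Z ranking recovers planted signal genes and is stable in n_boot", {
  cfg <- simulation_config(seed = 17, n_genes = 400, n_signal_genes = 20,
                           beta_signal = 2)
  geom <- make_parcellation_geometry(34, 6, seed = 17)
  set.seed(17)
  y <- fix_smooth_map(geom)
  X <- simulate_expression(geom, y, cfg)
  sig <- attr(X, "signal_genes")

  rk <- bootstrap_gene_z(X, y, n_boot = 200, seed = 8)
  top <- rk$gene[order(-abs(rk$z))][1:ceiling(0.1 * nrow(rk))]
  expect_gte(mean(sig %in% top), 0.9)
  expect_true(all(diff(rk$z) <= 0))
  expect_true(all(rk$se > 0))

  rk2 <- bootstrap_gene_z(X, y, n_boot = 400, seed = 9)
  common <- intersect(sig, rk2$gene)
  z1 <- rk$z[match(common, rk$gene)]
  z2 <- rk2$z[match(common, rk2$gene)]
  expect_lt(median(abs(z2 - z1) / abs(z1)), 0.1)

  # exact copy of the map dominates the first-component weights
  X2 <- cbind(X, exact_copy = as.numeric(scale(y)))
  f <- pls_fit(X2, y, n_components = 1)
  expect_equal(names(which.max(abs(f$weights[, 1]))), "exact_copy")
})

test_that("enrichment scores match brute force and respond to set placement", {
  set.seed(23)
  for (n in c(6, 8)) {
    scores <- sort(rnorm(n), decreasing = TRUE)
    combos <- utils::combn(n, 3)
    for (j in seq_len(ncol(combos))) {
      in_set <- seq_len(n) %in% combos[, j]
      mine <- plexitome:::running_es(scores, in_set)$es
      expect_equal(mine, brute_es(scores, in_set), tolerance = 1e-12)
    }
  }

  # top-k set scores positively, spread set weakly, reversal negates ES
  rk <- data.frame(gene = sprintf("g%02d", 1:20), z = seq(3, -3, length.out = 20))
  top <- list(topset = rk$gene[1:5])
  res_top <- gsea_preranked(rk, top, n_perm = 400, seed = 3)
  expect_gt(res_top$es, 0)
  spread <- list(spreadset = rk$gene[c(1, 5, 9, 13, 17)])
  res_sp <- gsea_preranked(rk, spread, n_perm = 400, seed = 3)
  expect_lt(abs(res_sp$es), abs(res_top$es))
  expect_gt(res_sp$p, 0.1)

  rev_rk <- data.frame(gene = rk$gene, z = -rk$z)
  es_f <- plexitome:::running_es(rk$z, rk$gene %in% top$topset)$es
  es_r <- plexitome:::running_es(rev(-rk$z), rev(rk$gene %in% top$topset))$es
  expect_equal(es_r, -es_f, tolerance = 1e-12)
})

test_that("enrichment agrees with the reference GSEA implementation on unweighted scores", {
  skip_if_not_installed("fgsea")
  set.seed(29)
  genes <- sprintf("g%03d", 1:100)
  z <- sort(rnorm(100), decreasing = TRUE)
  rk <- data.frame(gene = genes, z = z)
  sets <- list(s1 = genes[c(2, 5, 8, 11, 14, 20)],
               s2 = genes[sample(100, 10)])
  stats_v <- stats::setNames(z, genes)
  ref <- fgsea::fgsea(sets, stats_v, nPermSimple = 2000, gseaParam = 1)
  mine <- gsea_preranked(rk, sets, weight_p = 1, n_perm = 500, seed = 1)
  for (nm in names(sets)) {
    expect_equal(mine$es[mine$set == nm], ref$ES[ref$pathway == nm],
                 tolerance = 1e-6)
  }
})

test_that("cell-type enrichment flags classes by FDR and handles single-class input", {
  cfg <- simulation_config(seed = 31, n_genes = 300, n_signal_genes = 15,
                           beta_signal = 2)
  geom <- make_parcellation_geometry(34, 6, seed = 31)
  set.seed(31)
  y <- fix_smooth_map(geom)
  X <- simulate_expression(geom, y, cfg)
  sig <- attr(X, "signal_genes")
  rk <- bootstrap_gene_z(X, y, n_boot = 150, seed = 4)

  classes <- list(Ex = sig,
                  In = sample(setdiff(colnames(X), sig), 15),
                  Ast = sample(setdiff(colnames(X), sig), 15))
  res <- cell_type_enrichment(rk, classes, n_perm = 500, seed = 6)
  expect_equal(res$set[which.max(res$nes)], "Ex")
  expect_true(res$significant[res$set == "Ex"])

  one <- cell_type_enrichment(rk, classes["Ex"], n_perm = 300, seed = 7)
  expect_equal(nrow(one), 1L)
  expect_equal(one$fdr, one$p)
})

test_that("gene sets and expression matrices round-trip through GMT and CSV", {
  genes <- sprintf("g%03d", 1:60)
  sets <- make_gene_sets(genes, signal_genes = genes[1:10], n_sets = 4,
                         set_size = 12, seed = 2)
  expect_named(sets)
  expect_true(all(genes[1:10] %in% sets$signal_set))
  f <- tempfile(fileext = ".gmt")
  write_gmt(sets, f)
  back <- read_gmt(f)
  expect_equal(lapply(back, sort), lapply(sets, sort))
  expect_error(write_gmt(stats::setNames(sets, rep("a", 4)), f), "format error")

  geom <- make_parcellation_geometry(12, 3, seed = 3)
  cfg <- simulation_config(seed = 3, n_regions = 12, n_genes = 30,
                           n_signal_genes = 5)
  X <- simulate_expression(geom, fix_smooth_map(geom), cfg)
  fx <- tempfile(fileext = ".csv")
  write_expression(X, fx)
  X2 <- read_expression(fx)
  expect_equal(unclass(X2), unclass(X)[, ], tolerance = 1e-10,
               ignore_attr = TRUE)
  fg <- tempfile(fileext = ".csv")
  write_geometry(geom, fg)
  g2 <- read_geometry(fg)
  expect_equal(g2$region, geom$region)
  expect_equal(g2$cortical, geom$cortical)
})

test_that("under a null map the spin-test p for PLS1 variance explained is roughly uniform", {
  geom <- make_parcellation_geometry(30, 5, seed = 41)
  cfg <- simulation_config(seed = 41, n_regions = 30, n_genes = 120,
                           n_signal_genes = 10, beta_signal = 0)
  set.seed(41)
  y0 <- fix_smooth_map(geom)
  X <- simulate_expression(geom, y0, cfg)
  Xs <- scale(X)
  ps <- vapply(1:60, function(i) {
    y <- rnorm(nrow(geom))
    spin_null(geom, y, function(yy) pls1_varexp(Xs, yy, scale = FALSE),
              n_perm = 200, seed = 500 + i)$p
  }, numeric(1))
  expect_gte(mean(ps < 0.05), 0.0)
  expect_lte(mean(ps < 0.05), 0.15)
  expect_gt(mean(ps), 0.3)   # not systematically anti-conservative
})
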