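# plexitome

Quantitative pipeline for studies linking **choroid-plexus (CP)
morphology to neuroinflammation**: the CP sits at the blood–CSF barrier,
and its enlargement has been tied to central inflammation measured by
TSPO PET. Testing that association requires a chain of quite different
computations — mask volumetrics, reference-tissue kinetic modelling of
dynamic PET, blood-to-CSF tracer-exchange indices, partial-volume
correction, covariate-adjusted cohort statistics, and a transcriptomic
decoder of regional association maps. `plexitome` implements that chain
as tested R functions, together with synthetic-data generators that
produce every input with known ground truth, so the full pipeline is
verifiable without access to subject data.

## What is inside

* **Kinetics** — `fit_srtm()` fits the simplified reference tissue model
  by basis functions: for the target curve
  `C_T = R1·C_ref + (k2 − R1·k2a)·C_ref ⊗ exp(−k2a·t)`,
  `k2a = k2/(1+BPnd)`, it scans a log-spaced `k2a` grid, solves the
  linear subproblem per grid point and reports `R1`, `k2`, `BPnd` and
  the distribution volume ratio `DVR = 1 + BPnd`.
  `supervised_reference()` extracts a non-inflamed grey-matter reference
  region by non-negative decomposition onto kinetic class curves.
* **Exchange indices** — `suvr_at_60()` and `auc_window()` (trapezoidal
  30–60 min integral) summarize tracer transfer into the lateral
  ventricles; `rl_deconvolve()` + `cp_dvr_pvc()` give a Richardson–Lucy
  partial-volume-corrected CP DVR (6 mm PSF, 10 iterations by default).
* **Volumetrics** — `mask_volume()`, 6-connected `erode_mask()`,
  `residualize()`, NIfTI mask I/O.
* **Cohort statistics** — pooled `two_sample_t()` from raw data *or*
  printed `{n, mean, sd}` summaries, `shapiro_wilk()`,
  `partial_correlation()` (covariate-residualized Pearson, df = n−2−k),
  `ancova_group_effect()` (Type-III group F), `adjust_pvalues()`.
* **Transcriptomic decoder** — `pls_fit()` (NIPALS PLS of a regional map
  on a regions × genes matrix), `spin_null()` (rotation-based spatial
  permutation with greedy nearest-neighbour reassignment, free
  permutation of subcortical regions), `bootstrap_gene_z()`
  (region-bootstrap gene-weight Z ranking) and `gsea_preranked()` /
  `cell_type_enrichment()` (local pre-ranked GSEA with permutation NES
  and BH FDR; GMT I/O).
* **Generators** — `simulate_srtm_tac()`, `simulate_dynamic_image()`,
  `simulate_cohort()` (planted group effect and partial correlations),
  `simulate_expression()` (spatially autocorrelated fields with planted
  signal genes), `make_gene_sets()`, `make_parcellation_geometry()`.

## Worked example

```r
library(plexitome)

## 1. Kinetics: forward-simulate a noisy target curve, fit it back
ref <- make_reference_tac(default_schedule(), peak_time = 5)
tt  <- simulate_srtm_tac(ref, R1 = 1.1, k2 = 0.10, BPnd = 0.4,
                         noise_cov = 0.05, seed = 42)
fit_srtm(tt, ref)
#> Simplified reference tissue model fit (basis functions)
#>   R1 = 1.1691   k2 = 0.1147 /min   k2a = 0.0780 /min
#>   BPnd = 0.4700   DVR = 1.4700   RSS = 0.2259

## 2. Cohort: adjusted group effect and partial correlation
sim <- simulate_cohort(simulation_config(seed = 42))
tab <- sim$table
ancova_group_effect(tab$log10_cp_volume, tab$group,
                    covariates = data.frame(icv = tab$icv))
#> ANCOVA group F: statistic = 6.305, df = 1, 73, p = 0.01425
partial_correlation(tab$log10_cp_volume, tab$dvr_CP,
                    cbind(tab$icv, as.numeric(tab$group)))
#> partial correlation (k = 2): statistic = 0.1883, df = 72, p = 0.1081

## 3. Decoder: planted signal genes in a synthetic transcriptome
geom <- make_parcellation_geometry(34, 6, seed = 42)
cfg  <- simulation_config(seed = 42, n_genes = 600, n_signal_genes = 30,
                          beta_signal = 2)
D <- as.matrix(dist(geom[, c("x", "y", "z")]))
y <- as.numeric(t(chol(exp(-D / 20) + diag(1e-8, 34))) %*% rnorm(34))
X <- simulate_expression(geom, y, cfg)
Xs <- scale(X)
sp <- spin_null(geom, y, function(yy) pls1_varexp(Xs, yy, scale = FALSE),
                n_perm = 1000, seed = 1)
sprintf("PLS1 explains %.1f%% of the map (spin p = %.3g)", 100 * sp$observed, sp$p)
#> "PLS1 explains 96.3% of the map (spin p = 0.000999)"

rk <- bootstrap_gene_z(X, y, n_boot = 500, seed = 2)
sets <- make_gene_sets(colnames(X), attr(X, "signal_genes"),
                       n_sets = 6, set_size = 30, seed = 3)
gsea_preranked(rk, sets, n_perm = 1000, seed = 4)
#>             set size    es   nes       p     fdr
#> 1    signal_set   30 1.000 2.079 0.00112 0.00675
#> 2 random_set_02   30 0.645 1.320 0.12471 0.37413
#> 3 random_set_03   30 0.484 1.000 0.51448 0.96970
#> ...
```

The fitted DVR (1.47 against a planted 1.4 at 5% noise), the adjusted
group F, the spin-test p at its add-one floor, and the planted gene set
winning the enrichment table with FDR < 0.05 are exactly the quantities
a real analysis of this design would report.

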