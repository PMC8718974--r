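---
title: "Methods: from dynamic TSPO PET to transcriptomic decoding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from dynamic TSPO PET to transcriptomic decoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plexitome)
```

`plexitome` implements the computational chain of a choroid-plexus /
neuroinflammation imaging study: regional volumetrics, reference-tissue
kinetic quantification of dynamic TSPO PET, covariate-adjusted cohort
statistics, and a transcriptomic decoder of a regional statistic map.
Because raw subject data of such studies are rarely shareable, every
input has a synthetic generator with known ground truth; all the
quantitative guarantees quoted below are computed by the package's own
test suite and acceptance script on those generators.

## Kinetic model

The tracer model is the simplified reference tissue model (SRTM). With a
reference-region concentration $C_{ref}(t)$, the target tissue curve is

$$C_T(t) = R_1\,C_{ref}(t) + \left(k_2 - R_1 k_{2a}\right)\,
  C_{ref}(t) \otimes e^{-k_{2a} t},\qquad k_{2a} = \frac{k_2}{1+BP_{nd}},$$

and the binding read-out is the distribution volume ratio
$DVR = 1 + BP_{nd} = k_2/k_{2a}$.

`fit_srtm()` uses the basis-function formulation: for each candidate
$k_{2a}$ on a grid of 64 log-spaced values in $[0.006, 0.6]$ min$^{-1}$
(bracketing plausible [¹¹C]PK11195 kinetics) the model is linear in
$(R_1,\,k_2 - R_1 k_{2a})$, so a two-parameter weighted least-squares
problem is solved per grid point and the residual-sum-of-squares
minimiser wins. Two numerical choices matter:

* **Quadrature.** The convolution is evaluated by exact integration of
  the piecewise-linear interpolant of $C_{ref}$ against the exponential
  kernel on a 0.1 min uniform grid, then averaged within frames —
  frame-averaged data is what a scanner reports, and the recursive
  update is stable for any $k_{2a}\,\Delta t$.
* **Grid refinement.** A finite grid leaves a DVR discretization bias of
  order the grid spacing (about 1% at 64 points). After the grid pass
  the fit refines $k_{2a}$ continuously between the two neighbouring
  grid points (`refine = TRUE`), which removes that bias; noiseless
  forward-simulated curves invert to machine precision. A solution on
  the grid edge is flagged `boundary` and not refined; a fitted
  $DVR \le 0$ is flagged `failed`.

Frames are weighted by duration by default, the usual variance proxy for
decay-corrected count data.

The forward simulator `simulate_srtm_tac()` shares the quadrature but is
exercised against the fitter as a round trip across a 36-point parameter
grid ($R_1 \in \{0.8,1,1.2\}$, $k_2 \in \{0.05,0.1,0.2\}$,
$BP_{nd} \in \{0,0.2,0.5,1\}$) in the acceptance suite. Its noise model
is zero-mean Gaussian with SD proportional to activity and to
$1/\sqrt{\text{frame duration}}$, the standard count-statistics
approximation.

The reference input is a gamma-variate rise-and-washout curve
(`make_reference_tac()`): no plasma input is modelled, matching the
reference-tissue setting where only the shape of $C_{ref}$ matters. The
default acquisition is 18 frames over 60 minutes (4×0.5, 4×1, 4×2, 2×3,
4×10 min); the schedule is a configuration choice, not a constraint.

## Reference-region extraction

`supervised_reference()` classifies grey-matter voxels by their
kinetics: each voxel's unit-mean-normalized time course is decomposed by
non-negative least squares onto four normalized class curves
(blood-like, normal grey, white-like, high-binding;
`kinetic_class_curves()`), and voxels whose normalized coefficient on
the normal-grey class exceeds 0.9 form the reference region. This is a
deliberately lean re-expression of supervised-cluster reference
extraction — four canonical classes and a hard threshold instead of the
full published machinery — and is documented as such; with synthetic
images containing a high-binding contaminant class, at least 95% of
selected voxels are true normal-grey voxels in the tests.

## Blood-to-CSF exchange indices and partial-volume correction

Two static indices summarize tracer exchange into the lateral
ventricles: `suvr_at_60()` (target/reference activity at the final
frame by default, a 50–60 min window by option — the phrase "at 60 min"
is genuinely ambiguous, so both readings are exposed) and
`auc_window()`, the trapezoidal integral of the ventricle curve between
30 and 60 min with frame midpoints as abscissae and linear edge
interpolation. The AUC is a raw integral; no dose or reference
normalization is applied unless requested, since the bare index is what
enters group statistics.

`rl_deconvolve()` is Richardson–Lucy restoration
$x \leftarrow x \cdot H\!\left(y / H x\right)$ with $H$ an isotropic
Gaussian of 6 mm FWHM (default) and 10 iterations. The blur operator
renormalizes its kernel at the volume boundary (division by the blurred
unit image), which makes constant images exact fixed points and
conserves total intensity to well under 0.1% for structures away from
the edge. Ten iterations is a deliberate early stop: RL converges to a
maximum-likelihood solution that amplifies noise if run long.
`cp_dvr_pvc()` then reads the mean of the deconvolved DVR map inside the
choroid-plexus mask.

## Volumetrics

`mask_volume()` is voxel count × voxel volume; `erode_mask()` iterates
6-connected (face-neighbour) morphological erosion, the most
conservative standard structuring element — two iterations of it on a
2.6 mm grid corresponds to the ~5.2 mm margin typically quoted for
ventricle erosion. Erosion that empties a mask raises an explicit
error rather than returning silence. `residualize()` is the
least-squares covariate-adjustment primitive shared by the statistics
layer; volumes destined for normality-based tests are carried as
$\log_{10}$ values.

## Cohort statistics

`two_sample_t()` is the pooled-variance Student t and accepts either raw
vectors or printed summaries $\{n, \bar x, s\}$ — published cohort
tables print only summaries, and the pooled t is exactly recomputable
from them (this is also why pooled, not Welch, is the default: the
printed t values of the motivating cohort reproduce only under pooled
variance; Welch is a flag). `partial_correlation()` correlates the two
covariate-residualized vectors with $df = n - 2 - k$; a variable fully
explained by the covariates yields $r = 0$ rather than numerical noise.
`ancova_group_effect()` reports the partial (Type-III) F for group,
which equals the squared pooled t when no covariates are present — an
identity the tests assert exactly. `shapiro_wilk()` wraps the standard
Royston approximation. `adjust_pvalues()` offers Bonferroni and
Benjamini–Hochberg; BH is the default for exploratory correlation
families.

## Synthetic cohort

`simulate_cohort()` generates a two-group table at the study scale (51
cases / 25 controls by default). Log₁₀ CP volume has marginal SD 0.11, a
0.25 correlation share from intracranial volume, and a planted group
shift of 0.46 SD — the effect size implied by the motivating cohort's
printed group means. Regional DVRs (and, with negative sign, the
exchange indices) are built from the CP-volume residual after ICV and
group so that their adjusted partial correlation with log₁₀ CP volume
equals the planted value (0.34 by default) in expectation. Clinical
scores and blood markers are group-shifted noise with realistic
location and spread. The generator is exactly calibrated under null
configurations: with no planted effect the downstream t-test rejects at
5% within binomial error over 500 replicate simulations.

What the generator does *not* emulate: non-Gaussian marker
distributions (CRP is heavily skewed in real cohorts), missingness
patterns, scanner batch effects, or any causal structure — passing
tests show the estimators recover planted parameters, not that real
effects of this size exist.

## Transcriptomic decoder

`pls_fit()` is NIPALS partial least squares of a regional map on a
z-scored regions × genes matrix; per-component fractions of map
variance are reported and, in the full-rank limit, sum to the OLS $R^2$
(asserted against an independent PLS implementation in the tests).
`pls1_varexp()` is the closed form for the first component, cheap
enough for permutation loops.

`spin_null()` builds the spatial null: cortical centroids are projected
to the unit sphere about their centroid, rotated by a uniform random 3D
rotation, and each region takes the map value of its nearest rotated
neighbour under greedy matching without replacement; subcortical
regions, which have no spherical embedding, are permuted freely — a
standard compromise whose fidelity for deep structures is unknown and
is documented as such. P-values use the add-one convention throughout,
so $p \ge 1/(1+n_{perm})$ and the test is never anti-conservative by
construction; its empirical size on isotropic maps is measured at
500 spins × 500 replicate maps in the acceptance suite.

`bootstrap_gene_z()` resamples regions with replacement, refits PLS1,
aligns each replicate weight vector's sign to the original by dot
product (PLS weights are sign-indeterminate), and ranks genes by
$Z = w / SE_{boot}$. Degenerate resamples (fewer than 3 distinct
regions, or a constant column) are redrawn and counted.

`gsea_preranked()` is local pre-ranked GSEA: running-sum enrichment with
$|Z|^p$ increments ($p = 1$ default), label-permutation null, NES by
same-sign mean normalization, and BH FDR across sets. The
enrichment score is verified against exhaustive brute-force computation
on all placements of a 3-gene set in rankings of up to 8 genes, and
against an independent reference implementation on larger instances.
`cell_type_enrichment()` applies it per cell class and flags classes
failing FDR < 0.05.

`simulate_expression()` draws background genes from a Gaussian field
over the parcel centroids with exponential covariance
$\exp(-d/\ell)$, $\ell = 20$ mm by default — matching the mesoscale
autocorrelation of cortical expression maps — and adds the target map
with coefficient `beta_signal` to a planted gene subset. The default
scale is 34 regions × 1500 genes: large enough for stable PLS and spin
geometry, small enough for desk-scale test runs; gene count is a
configuration knob, and nothing in the method depends on it.

## Problem sizes and determinism

The shipped tests and acceptance script run at: 36-point SRTM grids with
200-replicate noise Monte Carlo; 30³-voxel phantoms; 500-replicate
calibration loops for the cohort generator, ANCOVA permutation and spin
size (500 spins each); 1000 bootstrap replicates and 1000 permutations
for the decoding chain at 34 regions × 1000 genes. These sizes were
chosen so each property is measured within tight binomial error while a
full run stays a desk-scale job. Every stochastic routine takes an
explicit seed and is bit-reproducible given it.

## Known limitations

* No scanner physics: attenuation, scatter, randoms, motion and
  registration are out of scope; inputs are assumed preprocessed.
* No arterial-input kinetic models; reference-tissue quantification
  only.
* The supervised reference uses synthetic class curves; applying it to
  real data requires measured class kinetics.
* The spin test's treatment of subcortical regions (free permutation)
  is a pragmatic convention, not a validated null for deep structures.
* The expression generator does not model donor effects, probe noise or
  hemispheric asymmetries of real atlas data.
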