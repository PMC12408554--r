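---
title: "Methods: models, parameters, and design choices in burnoutmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters, and design choices in burnoutmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the statistical machinery: the
models each stage assumes, the parameters that matter and why their defaults
are what they are, what the synthetic-data generators do and do not emulate,
and the numerical conventions adopted where the underlying methods leave
room.

## 1. Spontaneous activity: fALFF and seed connectivity

A voxel's BOLD series `x(t)` (T timepoints at repetition time `tr` seconds)
is linearly detrended and Fourier-transformed. The one-sided amplitude
spectrum uses Parseval-consistent scaling — the sum of squared amplitudes
equals `sum(x^2)` — so the spectral decomposition is exactly
energy-preserving, which gives the test suite a closed-form oracle.

**fALFF** is the ratio of summed square-root power in the low-frequency band
(default 0.01–0.1 Hz) to the summed square-root power over the analyzed
range (default 0.01–0.25 Hz). Two conventions were open:

* *Ratio of sums, not ratio of means.* With the band nested in the total
  range, the ratio-of-sums lies in [0, 1] by construction and matches the
  original fALFF definition; a ratio of band means would not be bounded by 1
  when bin counts differ. This is the package's convention everywhere.
* *Closed band edges.* A bin at frequency `k/(T·tr)` belongs to a band iff
  `low ≤ f ≤ high`. At T = 240, tr = 2 s the choice moves at most one bin
  and is documented rather than influential.

Degenerate voxels (zero total-band power, e.g. constant series) return
fALFF 0 with a warning, so masks containing padding voxels do not poison a
map with NaN.

**Standardization.** The pipeline applies Fisher's transform
`z = atanh(v)` to fALFF maps — valid because fALFF ∈ [0, 1) — and to
correlation maps. Values with `|v| ≥ 1 − 1e-7` are clipped first; the clip
bound doubles as the "self-correlation" ceiling in degenerate synthetic
inputs (a voxel identical to the seed mean reports `atanh(1 − 1e-7)`).
An alternative mean/SD z-scoring across in-mask voxels is available
(`method = "zscore"`) but off by default: the Fisher transform is what the
emulated analysis names, and the two differ only by a monotone map within
subject.

**Seed FC** correlates the unweighted mean series of the seed cluster with
every in-mask voxel; no detrending or filtering is applied inside
`seed_fc_map()` itself (acquisition-level preprocessing is out of scope;
`detrend_linear()` and `nuisance_regress()` are provided as minimal
utilities for callers who need them).

## 2. Group inference: permutation cluster-level FWE

Between-group differences are assessed voxelwise by OLS on the design
(intercept, group contrast burnout = 1, age, education, TIV, BAI, BDI), with
`t = contrast / SE`, `df = n − 7`. Voxels with zero residual variance give
`t = 0` when the contrast estimate is also zero (identical maps carry no
evidence) and `NaN` otherwise.

Cluster-level correction is *nonparametric*: clusters are formed at a
two-sided voxel threshold (default p < 0.001), and the null distribution of
the per-tail **maximum cluster size** is built by Freedman–Lane permutation:
the maps are residualized on the nuisance covariates, residual rows are
permuted, and the full model is refit. `p_fwe = (1 + #{null ≥ size}) /
(n_perm + 1)` never returns zero and is deterministic given the seed. The
parametric Gaussian-random-field correction used by SPM-style software was
deliberately not reimplemented: it requires smoothness estimation that is
meaningless on synthetic desk-scale grids, whereas permutation FWE is
exactly testable — the suite verifies the family-wise error rate on 200
null cohorts against the binomial confidence band and the power to recover
a planted amplitude reduction.

Connectivity defaults to the 18-neighborhood (faces + edges, the SPM
convention; 6 and 26 available). Peak ties resolve to the lowest linear
voxel index, making reports reproducible bit-for-bit.

## 3. Clinical correlation

Cluster summaries (unweighted means of finite in-cluster voxels) are
correlated with EE, DP and PA by plain Pearson correlation; two-sided
p-values use the Student-t transform with `n − 2` degrees of freedom. No
covariate partialling is applied — the printed coefficients of the emulated
study are numerically consistent with df = 49 at n = 51, confirming plain
correlation — and no multiplicity correction by default (a Benjamini–
Hochberg option exists behind `adjust = "BH"`).

## 4. Expression pipeline

The AHBA-style processing chain, in order: intensity filter (probe kept iff
above background in ≥ 50% of samples pooled across donors, boundary
inclusive); RNA-seq-guided probe selection (genes absent from the RNA-seq
reference dropped; probes with microarray/RNA-seq correlation r < 0.2
dropped; per gene the highest-r probe kept, ties to the lexicographically
smaller probe id); restriction to left-hemisphere samples falling inside a
nonzero atlas voxel (nearest-voxel lookup, no search radius — "located
within" is taken literally; a tolerance could be added behind config);
scaled robust sigmoid normalization; differential stability (DS) selection
of the top 50% of genes.

**SRS details.** `s = sigmoid((x − median)/(IQR/1.35))` rescaled to [0, 1]
by its own range; IQR uses type-7 (linear interpolation) quantiles, the
most common default. The sigmoid is computed as a `tanh`, whose bit-exact
odd symmetry pins symmetric inputs to exactly 0.5 at the median —
`srs_normalize(c(1, 2, 3))` is exactly `c(0, 0.5, 1)`. Constant input maps
to all 0.5; zero IQR with non-constant input falls back to the standard
deviation as scale. Normalization runs within-sample across genes first,
then within-gene across samples, matching the stated order of the emulated
pipeline; both passes are applied donor-wise by default (`srs_scope =
"donor"`) to mitigate donor effects — whether the original analysis pooled
donors is unstated, so the pooled variant is one argument away.

**DS details.** DS is the mean over donor pairs of the Spearman correlation
between the two donors' region-mean expression profiles over shared regions
(rank correlation because donors differ in dynamic range; pairwise-complete
because they differ in sampled regions; pairs sharing fewer than 3 regions
are skipped). DS is a *between-donor consistency* measure: it needs enough
atlas regions to rank genes stably — the test suite uses 32–64 regions.

## 5. Spatial surrogates and ensemble-based GCEA

Gene scores are Pearson correlations between each gene's expression and the
t-map values at the tissue-sample locations (mean over voxels within a 3 mm
sphere, boundary inclusive; locations with no finite voxel are dropped with
a warning). Categories with 10–200 scored members are scored by the mean of
their members' gene scores.

Significance comes from a **neuroimaging-spatial ensemble null**: surrogate
maps that preserve the original map's value multiset and spatial
autocorrelation, on which gene scores and category scores are recomputed.
Two generators are implemented:

* `"spatial_lag"` — `y = (I − ρW)^{-1} z` with `W_ij = exp(−d_ij/d0)`, zero
  diagonal, row-normalized; then rank-remapped onto the original values.
  This is the generative model named for this class of nulls, and it is the
  package default in `fit_spatial_lag()`/`generate_surrogates()`.
* `"variogram_match"` — permute the values, smooth the permutation with a
  Gaussian kernel of scale `d0`, blend smoothed and permuted components
  with weight `ρ`, rank-remap.

Both satisfy the same invariants (exact multiset preservation, determinism
per seed; `ρ = 0` reduces to plain permutation). They are *not*
interchangeable in representational power: on scattered sample geometries
the row-normalized lag operator concentrates its gain on a few global
smooth eigenmodes, so its realizations have weak, unstable short-range
autocorrelation — it cannot mimic a strongly smooth map. The
variogram-matching generator smooths locally and can. For this reason the
high-level receptor wrapper (`neuromap_association()`) and the calibration
checks fit with `generator = "variogram_match"`; the lag model remains
available and is the default of the low-level API. Both fits select
`(ρ, d0)` by pilot-surrogate grid search minimizing the squared *relative*
error between mean surrogate variogram and observed variogram (10
log-spaced bins between the 5th and 95th percentile of pairwise distances;
relative error weights every bin equally on its own scale), followed by a
local refinement pass; near-ties (within 50%, i.e. within pilot Monte-Carlo
noise) resolve to the smallest `ρ` so that spatially unstructured maps fit
`ρ = 0`.

The two-sided category p-value is `2·min(tails)` with add-one smoothing,
capped at 1 — conservative and never zero. Null category scores for all
surrogates are computed as one standardized cross-product (genes ×
surrogates), which keeps thousands of surrogates tractable; the identical
code path scores the original map, so observed and null scores are exactly
commensurable.

**Calibration behavior.** Under null expression the *rejection rate* of
category tests sits at the nominal level (verified at α = 0.05 over 500
synthetic categories). Conditional on a single map realization, category
p-values are mutually dependent (they share the map and overlap in genes),
so a per-realization uniformity test fluctuates — individual realizations
tilt slightly conservative or liberal even when the marginal rate is
nominal, and residual conservatism reflects surrogate ensembles that are
never narrower than the fitted model class allows. This is a property of
ensemble nulls generally, not of this implementation.

## 6. Receptor-map association

Maps are reduced to region means over the atlas (finite voxels only; empty
regions excluded pairwise). The association between the t-map profile and a
receptor profile is the Pearson correlation of residuals after both are
regressed (with intercept) on region-mean gray-matter probability —
symmetric partial correlation, removing tissue-fraction confounding; it
equals the plain correlation when the gray-matter profile is constant, and
a profile that is an exact linear function of gray matter is orthogonal to
everything (partial r = 0). P-values are two-sided on |r| against
surrogates of the t-map profile generated at the region-centroid geometry —
so "adjusted for spatial autocorrelation" means the null respects the
t-map's spatial structure. With constant gray matter and ρ = 0 surrogates
this converges to the classical permutation test, which the suite verifies
against exhaustive enumeration at 7 regions.

## 7. What the generators emulate — and what they do not

`gen_bold_cohort()` (defaults: two groups of 51 subjects, 240 timepoints at
TR = 2 s, 3 mm voxels, mirroring the emulated study's demographics table)
builds each voxel series as AR(1) Gaussian noise (lag-1 correlation 0.3,
unit marginal SD) plus a shared band-limited oscillation — five unit-power
sinusoids at frequencies uniform in 0.02–0.08 Hz, safely interior to the
0.01–0.1 Hz band at these acquisition parameters — whose amplitude in one
parcellation region is scaled by group (`amplitude_ratio`, default 1.5:
controls above burnout, the direction of the emulated finding) and by a
per-subject factor. MBI subscales couple to that factor through a Gaussian
copula (target |r| = `clinical_coupling`, default 0.3, near the printed
clinical correlations): EE and DP negatively, PA positively; score
marginals follow the study's demographic table by group. The parcellation
is a configurable block partition of the grid interior (8 octants by
default; `region_splits = c(5, 6, 3)` gives an AAL-90-like region count).

`gen_expression_bundle()` (defaults: 838 samples, 5013 genes entering the
pipeline, 6 donors, 20 mm autocorrelation length) draws sample locations at
distinct in-mask voxels (hemisphere from the sign of MNI x), builds gene
profiles as Gaussian random fields, mixes `planted_genes` with the
reference map to a target spatial correlation, and adds donor-specific
noise at the donor × spatial-block level — block-level, because noise that
is independent per sample would average away in region means and leave
differential stability unable to rank genes. Planted genes get the lowest
donor noise so they survive the DS filter *when the reference map is
spatially smooth*; a spatially white reference has no donor-consistent
regional structure to inherit, so planted genes would be penalized — the
tests therefore plant against smooth reference fields, as a real t-map is.
Decoy probes are constructed to fail exactly one filter each: above
background in only 40% of samples (intensity), or uncorrelated with the
RNA-seq reference (probe selection).

`gen_receptor_maps()` paints region-level mixtures
`r·z(reference) + sqrt(1−r²)·noise` onto the parcellation (plus zero-mean
within-region jitter), so the achieved region-level correlation is the
target up to `1/sqrt(n_regions)` sampling noise — the construction is
verified to ±0.1 at 90 regions.

None of the generators model hemodynamic response, physiological noise,
motion, scanner drift, inter-regional connectivity structure, realistic
gene co-expression modules, or GO-hierarchy structure (annotations are
direct, as the enrichment method assumes). Passing tests therefore
demonstrate the *statistical machinery* — calibration, power against
planted effects, exactness of deterministic transforms — not performance on
real acquisitions.

## 8. Problem sizes and numerical conventions

The test suite runs its stochastic checks at deliberately small scale: null
and planted cohorts on 12³ grids with 120 timepoints and 500 permutations
(200 null replicates for the family-wise error check, 20 seeds for power);
GCEA calibration with ~500 categories and 1000 surrogates on ~350-sample
bundles; surrogate fidelity at 150 locations and 500 surrogates. These
sizes were chosen as the smallest at which the binomial confidence bands
and power targets are meaningful; all scale linearly upward on real data
(`n_perm = 5000` and 10,000 surrogates reproduce the emulated study's
settings).

Fixed conventions, collected: voxel indices are 0-based in world-coordinate
math; all distances are MNI millimetres through the affine; correlations
are clipped at `1 − 1e-7` before `atanh`; permutation p-values use add-one
estimators and never return 0; peak and probe ties break
deterministically (lowest voxel index, smallest probe id); every stochastic
function takes an explicit integer seed and records it in its output.

## 9. Known limitations

* Acquisition preprocessing (slice timing, realignment, normalization,
  smoothing) is out of scope; only linear detrending and nuisance
  regression ship as utilities.
* The spatial-lag surrogate generator under-represents strong smoothness on
  scattered geometries (Section 5); use the variogram-matching generator
  when the observed variogram is steep.
* Ensemble-null category tests are mildly conservative by construction, and
  per-realization p-value distributions are dependent; calibration
  statements are about marginal rates.
* The cluster-report fixtures verify the reporting machinery against the
  published cluster tables; the published voxelwise group results, GO term
  lists and receptor correlations themselves require the original
  non-redistributable data and are not recomputation targets.
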