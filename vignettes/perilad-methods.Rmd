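---
title: "Methods: quantifying chromatin tethering at the plant nuclear periphery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying chromatin tethering at the plant nuclear periphery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(perilad)
```

# Scope and model

perilad implements the quantitative machinery needed to ask whether
lamin-like proteins tether chromatin at the nuclear periphery (NP) of plant
2C nuclei: radial positioning statistics from 3D microscopy, Hi-C
compartmentalization metrics, regression of NP-interaction signal on
epigenomic features, and broad-domain (PLAD) calling from ChIP enrichment.
Because the raw microscopy and sequencing data behind such a study are not
distributable, the package ships a synthetic-data module whose generators
reproduce the *statistical structure* each analysis stage assumes. All
guarantees quoted below are computed by the test suite and
`scripts/acceptance.R`, not asserted.

# Synthetic data: what is emulated, and what is not

**Nuclei.** Sorted 2C nuclei are close to spherical, so nuclei are
axis-aligned ellipsoids rasterised onto an anisotropic voxel grid (default:
2.5 µm radius, 0.1 µm isotropic voxels, DAPI level 200 over background 5,
optional Poisson shot noise). The ellipsoid keeps the geometry analytic:
volume, shell fractions and the distance field all have closed forms to
test against.

**Radial signal placement.** FISH/painting signal is either `uniform` in
the interior or `boundary_bias`: a uniformly drawn candidate voxel at
boundary distance $d$ is accepted with probability
$\propto e^{-d/\beta}$. Both limits are checkable — $\beta \to \infty$
recovers the uniform law (two-sample KS against a uniform draw), and
$\beta \to 0$ concentrates essentially all mass in the outermost shell.
The acceptance envelope is rescaled by its interior maximum; this leaves
the target distribution untouched while keeping rejection sampling
practical at small $\beta$ (voxel-level distances are bounded below by one
voxel). No study provides a quantitative estimate of how strongly
NP-enriched chromatin is boundary-biased; $\beta$ is a free synthetic
parameter, and $\beta = 0.3$ µm is used as the "wild-type Green probe"
condition throughout because it produces the strong-but-not-degenerate
contrasts seen in real FISH tables.

**Hi-C.** Expected counts are
$\mu_{ij} = c\,(|i-j|+1)^{-\alpha}\,(1 \pm s)$ — $1+s$ for same-compartment
pairs, $1-s$ otherwise — Poisson-sampled and symmetrised, with $c$
calibrated so the expected total is `mean_depth * n_bins^2`. $s$ is the
single compartmentalization dial: $s=0$ removes all label dependence,
$s=1$ forbids cross-compartment contacts.

**Read-count tracks.** Treatment windows are Poisson at `depth` outside
planted domains and `depth * enrichment_fold` inside (partial overlaps
scale linearly); the control is Poisson(`depth`). Sequencing noise is
Poisson rather than negative-binomial — sufficient for the calibration and
recovery properties tested; a Gamma-mixing `overdispersion` multiplier is
available but off by default.

What the generators do **not** emulate: optical PSFs and chromatic
aberration, nucleoli and chromocenters, polymer-physics contact structure,
mappability and GC biases, or biological replicate variability. Passing
tests therefore demonstrate the correctness and calibration of the
*estimators* under their stated models, not robustness to every artefact of
real data.

# Imaging pipeline

**Segmentation** is a deliberately deterministic replacement for
interactive boundary tracing: one global Otsu threshold over the full DAPI
voxel histogram, the largest 3D connected component (6-connectivity,
per-slice labelling merged across slices), then per-z-slice hole filling.
On noisy synthetic nuclei this recovers the analytic mask with Jaccard
index ≥ 0.98.

**The distance field** operationalises "distance to the edge of DAPI
staining" as an exact anisotropic Euclidean distance transform: each
interior voxel's distance (µm) to the nearest voxel outside the mask, with
off-grid space counting as outside. The implementation is the separable
squared-distance scan, written in-package because no installed package
offers an exact anisotropic 3D EDT; it is verified *exactly* against
exhaustive nearest-outside search on random masks.

**Spots** are thresholded at a fraction of the within-mask channel maximum
(default 0.2), filtered to ≥ 4 voxels, and summarised by their
intensity-weighted barycenter; the NP distance is the trilinear
interpolation of the distance field at the barycenter. Distance is
measured from the barycenter (not the spot edge), and a barycenter that
interpolates to a non-positive distance is reported as 0 with a flag —
never negative. The default distance is the true 3D distance;
`distance_mode = "2d"` measures within the barycenter's focal plane only,
matching workflows that read distances off a single confocal section. The
2D distance equals the 3D one at the equator and overstates it near the
poles, which is why the mode matters for comparisons across nuclei.

**Group comparison** uses the two-sided Mann-Whitney *U* test with normal
approximation and tie correction (the conservative default when the
original analysis reports only significance thresholds), with summaries
formatted `mean ± sd, n` and codes `**` (p < 0.01), `*` (0.01 ≤ p < 0.05),
`ns`. Calibration: with both channels uniform, the test rejects at the
0.05 level in ~5% of 1000 simulated nucleus pairs; with $\beta = 0.3$ µm
vs uniform at 50 spots per group it rejects at 0.01 in > 90% of runs.

**Morphology.** Volume is voxel count × voxel volume. Surface area uses
the co-area identity — the integral of the gradient magnitude of a
Gaussian-smoothed mask indicator (σ = 1.5 voxels) — rather than a
marching-cubes mesh: no installed package provides marching cubes, and the
co-area estimator is simpler, anisotropy-aware and accurate to ~0.01% on a
digital 2.5-µm sphere at 0.05-µm voxels. Sphericity is Wadell's
$\pi^{1/3}(6V)^{2/3}/A$, capped at 1 (discretisation can push a perfect
sphere's estimate fractionally above 1).

# Chromosome painting and P0.5

The cumulative profile accumulates voxel intensity (default) or binarised
signal as a function of boundary distance over mask voxels, on a 0.05-µm
grid with linear interpolation; `p05` is the value at 0.5 µm. The lowest
two z-slices of the mask's bounding box are excluded by default, because
the nuclear part flattened against the slide distorts distances there;
excluding slices never changes the profile of signal lying entirely above
them (tested). The paired Green/Red comparison is the two-sided Wilcoxon
signed-rank test on per-nucleus `p05` differences with zero differences
dropped (Wilcoxon's original rule — ties are likely on coarse grids), plus
the count of nuclei with Green > Red. Under a shared radial model the test
rejects at 0.05 in ≤ 7% of simulations.

# Hi-C compartments

**Balancing.** ICE divides each entry by its (mean-normalised) row and
column marginals until the maximum relative marginal deviation drops below
`eps = 1e-4`. The correction factors are square-root damped: plain
marginal division enters a two-cycle on near-bipartite structures (e.g.
the $s = 1$ matrix, where cross-compartment entries vanish) and never
converges; damping reaches the same fixed point. Bins in the lowest 2% of
raw coverage are masked first. Balancing is idempotent and inverts a
constructed multiplicative bias to < 1e-3 relative error.

**O/E and correlation.** Expected counts per separation are means over
retained entries of each diagonal, so every diagonal of the O/E matrix
averages to 1 by construction. Compartments come from the leading
eigenvector of the Pearson correlation matrix of O/E rows — the standard
convention where "PCA" is reported without specifics; the eigenvector's
sign is oriented by a user-supplied track (ground-truth labels in
simulations; gene density or an active mark on real data, since no
universal orientation rule exists). Label A means oriented $e_i > 0$.

**Strength.** Cross-compartment (A–B) O/E values for bin pairs within
1 Mb are "distance-normalised interaction strengths relative to the
average" by the per-diagonal identity above, so no further normalisation
is applied; the mean A–B O/E rises toward 1 as compartmentalization
weakens, and two genotypes are compared by a two-sided Mann-Whitney test
on their A–B O/E sets. At the simulation conditions used throughout
(250 bins of 20 kb, mean depth 100), the mean A–B O/E increases strictly
as $s$ falls through 0.8, 0.6, 0.4, 0.2, 0, while call accuracy saturates
at 1 from $s = 0.2$ — accuracy is monotone but not strictly so, which is
why the test asserts strict monotonicity only for the strength statistic.

# NP-interaction regression

LASSO fits use glmnet with its defaults mirrored explicitly: internal
standardization, a 100-point log-spaced λ grid down to $10^{-4}\lambda_{max}$,
tenfold cross-validation, and the one-standard-error rule (`lambda.1se`,
the largest λ whose CV error is within one SE of the minimum). Fold
assignment is seeded-random by default; `fold_method = "contiguous"`
assigns contiguous blocks instead, which respects genomic autocorrelation.
Feature-set comparisons train on designated chromosomes and evaluate mean
squared error on held-out chromosomes, with standardization learned on the
training windows only. Distance to the pericentromere is measured from the
window midpoint (the anchor is otherwise unspecified) and is 0 for windows
overlapping a PR. KKT conditions of returned solutions are verified
numerically, and the λ→0 limit agrees with ordinary least squares.

# PLAD calling

The island caller is SICER-inspired, not a bit-compatible SICER
reimplementation — only the W/G/FDR semantics are fixed (W = 500 bp
windows, gaps ≤ G = 1500 bp bridged, islands kept at FDR < 0.01). Two
choices required care to keep the caller honest under the null:

* **Background rate.** A window's Poisson rate is the depth-scaled control
  value *floored at the depth-scaled genome-wide control mean*. Without
  the floor, chance dips of the control manufacture significance (the
  plug-in two-Poisson comparison is anti-conservative), and null
  simulations yield spurious islands several times too often.
* **Multiplicity.** Windows are screened at p < 0.2 (exposed as
  `screen_p`), merged into candidate islands, and island p-values (upper
  tail of summed treatment counts vs summed background) are
  Benjamini-Hochberg-corrected **with the total window count as family
  size**: candidate islands exist only because their windows passed
  screening, so correcting over islands alone understates the number of
  implicit tests and inflates the family-wise error ~6-fold in null
  simulations.

With both choices, ≤ 2% of 200 null simulations produce any island at
FDR 0.01, while planted 10-kb domains at fold 8 over depth 20 are
recovered with base-pair Jaccard ≥ 0.9, monotone in enrichment fold.

Log-ratio tracks use `log2((t + pc) / (s·input + pc))` with pseudocount 1;
`s` defaults to the ratio of track totals and can be overridden (pass 1
for depth-matched libraries). Accessibility contrasts partition windows
into domains vs 1-kb flanks (clipped at chromosome ends and neighbouring
domains) and compare by Mann-Whitney; peak-overlap stratification uses
half-open interval semantics throughout (an abutting window does not
overlap). qPCR fold enrichment is the ΔΔCt rule against a reference locus
assuming doubling per cycle.

# Numerical and implementation notes

* Interval arithmetic is 0-based half-open everywhere on disk (BED) and in
  data frames, converted to 1-based GRanges internally.
* All generators are pure functions of their seed; statistical tests in
  the suite fix seeds, and the acceptance script derives every stream from
  its `--seed`.
* Problem sizes used by the default test run and acceptance script —
  58³-voxel nuclei, 1000/200-replicate calibration and power runs,
  250-bin contact matrices, n = 3000/K = 30 regression problems, 200-seed
  island-caller nulls on 4000-window chromosomes — were chosen to give
  stable rates (binomial SE ≲ 1%) while keeping the whole suite in a few
  minutes on one CPU.
* Degenerate inputs are handled explicitly: constant DAPI or empty masks
  error; all-tied test inputs report p = 1 rather than NaN; constant
  feature columns are dropped with a warning; a degenerate top eigenvalue
  is flagged on the compartment call but labels are still emitted.

# Known limitations

The imaging stack assumes a single connected nucleus per stack and does
not model deconvolution, nucleolus exclusion or chromocenter structure.
The Hi-C module calls compartments per chromosome arm at one resolution at
a time and does not call TADs or loops. The island caller's background
model is Poisson; strongly overdispersed real ChIP input may need the
overdispersion option and a recalibrated `screen_p`. Whether real painting
analyses weight by raw intensity or thresholded signal is configurable
(`binarize`) because the convention varies between laboratories.
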