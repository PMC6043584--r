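---
title: "Stationary and dynamic functional connectivity under graded anesthesia: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stationary and dynamic FC under graded anesthesia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dfcstates)
```

## The problem

Volatile anesthetics such as isoflurane reshape the brain's functional
networks in a dose-dependent way. Two effects are repeatedly reported in
rodent resting-state fMRI: (i) the *stationary* correlation between
homotopic (left/right mirror) cortical regions weakens as the dose rises,
and (ii) the *dynamic* repertoire of whole-brain connectivity shifts from
states with modular structure (distinct network blocks interacting) toward
a spatially unstructured state of widespread uniform correlation.
`dfcstates` implements the analysis pipeline needed to quantify both
effects — stationary correlation networks with permutation inference, and
sliding-window dictionary learning of dynamic functional states (dFS) —
together with a seeded generator of synthetic dose cohorts with exported
ground truth, so that every stage of the pipeline has a recoverable target.

## The synthetic cohort generator

The generator emulates a dose-escalation experiment: groups of `nSubjects`
scans at dose levels 1.1, 1.3, 1.5 and 2.0 % isoflurane, each scan a
360-timepoint (TR = 1 s) multivariate series over 24 regions organised as
12 left/right homotopic pairs within five modules (LCN, ACN, PFN, SuCN,
ThN — lateral cortical, associative cortical, prefrontal, subcortical and
thalamic networks).

**Latent states.** Each timepoint is drawn from one of six latent
correlation-matrix states: four *modular* states built from module-pair
interactions (cortical LCN–ACN; subcortical SuCN–LCN; prefrontal PFN–ACN;
thalamo-prefrontal ThN–PFN), one globally *homotopic* state, and one
*unstructured* state with uniform off-diagonal correlation 0.30. The
distinct module-pair design keeps the states' edge-space vectors from
being near-collinear, which is what makes their weights separately
estimable by least squares. Block constructions that are not positive
semi-definite are projected to the nearest PSD matrix by eigenvalue
clipping (the projection distance is recorded on the object) and restored
to unit diagonal.

**Dose acts in two independent ways.**

* *Stationary:* every state's homotopic edges carry an "excess" above the
  state's structural background; this excess is scaled by
  `homotopicRho(dose) / homotopicRho(lowest dose)`. The default map takes
  the homotopic correlation from 0.70 at 1.1 % down to 0.15 at 2.0 %.
* *Dynamic:* the occupancy simplex over the six states shifts from the
  modular states (0.25/0.23 for the two leading modular states at 1.1 %)
  toward the unstructured state (0.71 at 2.0 %).

**Latent dynamics.** States switch in segments with geometric dwell times
of mean 40 timepoints, comparable to the analysis window so that states
are resolvable. By default each scan's total time per state is fixed at
`occupancy * T` by largest-remainder apportionment and the geometric
segments are interleaved in random order (`quota = TRUE`). The motivation:
with T = 360 and mean dwell 40 a scan contains only ~9 segments, so a
free-running multinomial draw would give each subject a realised occupancy
with a coefficient of variation near 60 % — an artifact of the short scan
that no empirical quantity constrains, and one that would dominate
between-subject variance of every downstream weight statistic. Treating
per-scan state exposure as a design quantity (and leaving `quota = FALSE`
available for free-running dynamics) keeps the dose effect on occupancy
the planted, recoverable signal.

**Hemodynamics and noise.** After state sampling, each region is smoothed
with a truncated Gaussian kernel of FWHM 1.0 s — the scale of the fast
rodent hemodynamic response at high field — and rescaled to preserve unit
variance; white noise of SD 0.1 is then added. These two parameters set
the sampling-noise floor of windowed correlation estimates: heavier
smoothing lowers the effective degrees of freedom per 40-sample window and
with FWHM ≳ 3 s the noise floor alone caps any 20-atom basis below half
the window-stack variance, which is inconsistent with the regime the
pipeline targets (20 atoms explaining > 50 %). The defaults keep the
cohort in that regime with margin.

**Reproducibility.** One master seed; every subject's sequence and signal
use sub-seeds derived deterministically from (dose index, subject index),
so any subset of the cohort reproduces bit-identically. In the
longitudinal design the same subjects recur across doses and each carries
a shared multiplicative modulation (SD 0.1) of its homotopic coupling; the
cross-sectional design draws distinct subjects per dose.

What the generator does **not** emulate: biophysical hemodynamics (no
balloon model), scanner artifacts (spikes, drifts), motion, volumetric
realism, or physiological confounds. Passing tests on these cohorts show
the pipeline recovers what it is designed to recover under clean,
correctly specified conditions — not that it is robust to the full
messiness of real acquisitions.

## Preprocessing

`highpassFilter()` implements high-pass temporal filtering as
Gaussian-weighted running-line (local linear) detrending with kernel scale
`sigmaS` seconds (default 75 s), the behavior of FSL's high-pass filter.
The contract is the transfer function, not a bit-match: constants and
ramps are removed almost exactly, a 10-s oscillation is retained within
5 %. Note that a running-line smoother is not a projection, so reapplying
the filter is only a near no-op (side lobes of order a few percent), and
the filtered series is explicitly demeaned. `varianceNormalize()` scales
each region to zero mean, unit variance. `dualRegression()` provides the
volumetric entry point: stage 1 regresses group spatial maps (plus
intercept) into each volume to give per-component time courses
(variance-normalised); stage 2 regresses those time courses into each
voxel's series to give subject-specific maps. The default stage order for
synthetic tables is highpass → variance normalise.

## Stationary FC

Full correlation networks are Pearson correlations over the whole scan;
partial correlation networks invert a ridge-regularised correlation matrix
(`ridgeRho = 0.1` on the correlation scale, chosen because the amount of
L2 regularisation used by FSLNets-style analyses is not standardised) and
convert the precision to partial correlations. Both are Fisher
z-transformed (`atanh`, entries clipped at |r| = 1 − 1e−7) for group
statistics. Matrices are ordered by the atlas (modules contiguous,
hemispheres interleaved) and `homotopicEdges()` extracts the 12 mirror-pair
values.

Group inference mirrors the field's split usage:

* `edgeGroupTest()` — unpaired pooled-variance t per edge, family-wise
  corrected by the permutation null of the maximum |t| over all edges
  (default 5000 permutations of the subject ordering; exact enumeration
  available for tiny groups). Tie handling adds the observed labelling to
  the null, so p ≥ 1/(P+1). Unpaired label exchange is the default even
  for the dose-escalation design; optional covariate columns (e.g. heart
  rate) are residualised out before testing.
* `anovaDoseEffect()` — one-way fixed-effects ANOVA per edge across all
  dose groups, BH-FDR across edges.
* `bhFdr()` — Benjamini–Hochberg step-up (a thin wrapper over
  `stats::p.adjust`), used for the atom-weight comparisons.
* `clusterEdges()` — average-linkage hierarchical clustering of regions
  under the distance 1 − |r|, exported as a Newick dendrogram.

## Dynamic FC

`slidingWindowFC()` slides a rectangular window (default 40 TR, step 1 TR)
across the series and vectorises the upper triangle of each window's
correlation matrix (row-major, i < j), Fisher z-transformed by default.
Rectangular (untapered) windows match the plain sliding-window protocol;
z-scaling stabilises the variance of window correlations. A window
containing a zero-variance region yields zero correlation on the affected
edges and is counted, not fatal.

`learnDictionary()` fits K unit-energy atoms (dynamic functional states)
by alternating minimisation of
\(\tfrac12\lVert X - D^\top A\rVert_F^2 + \lambda \lVert A\rVert_1\):
exact coordinate-descent sparse coding given the atoms, then a block
coordinate dictionary update with each atom solved in closed form and
projected onto the unit ℓ2 ball, so the objective is non-increasing
(checked to 1e−8 in the tests). On exit atoms are rescaled to exactly unit
norm (codes absorb the scale), signed so each atom's largest-magnitude
entry is positive, and ordered by usage. The penalty defaults to
\(\lambda = 0.1\,\mathrm{mean}(|D_0 X|)\) — about a tenth of a typical
atom-window inner product — since no sparsity level is standard; it is
exposed in every entry point. Unused atoms are re-seeded from the
worst-reconstructed window.

Robustness comes from folds: `learnConsensusDictionary()` runs the fit
`folds` times (fold f seeded `seed + f`), matches every fold to the first
by the Hungarian assignment maximising total |Pearson correlation| between
atom pairs (sign flips applied where the matched correlation is negative),
averages the aligned atoms, and renormalises. Per-atom stability is the
mean matched |correlation| across folds. Absolute correlation is used as
the similarity because dictionary atoms carry an intrinsic sign ambiguity.

`backfitWeights()` projects every window onto the atoms by unpenalised
least squares; the per-atom scalar summary is the mean absolute weight
over windows (the "mean absolute sum" of the state's fluctuations —
adopted reading: mean over windows of |weight|, stated here because the
quantity is often named but rarely defined). `varianceExplained()` reports
\(1 - \lVert X - D^\top A\rVert_F^2 / \lVert X - \bar X\rVert_F^2\) with
the back-fitted weights. `compareWeights()` runs per-atom two-sample
t-tests on the summaries with BH correction across the K atoms, and
refuses to compare weights fitted against dictionaries with different
ordering tags — the fixed atom ordering that makes "atom k" mean the same
state in both groups.

## Numerical choices and edge cases

* PSD projection tolerance 1e−8 on the minimum eigenvalue; projection
  distances recorded.
* Fisher transform clips |r| at 1 − 1e−7 and counts clipped entries.
* Zero pooled variance in a t-test is floored at machine epsilon and the
  edge flagged; a zero-variance region is an error in stationary FC (the
  correlation is undefined) but only a flagged degenerate window in
  sliding-window FC.
* Dendrogram and ranking ties break deterministically by lowest index.
* The Hungarian solver is the O(n³) shortest-augmenting-path formulation,
  exact for the K ≤ 30 matchings used here (verified against exhaustive
  permutation search at small K).
* All stochastic steps (simulation, permutation, fold initialisation) take
  explicit seeds and restore the caller's RNG state.

## Problem sizes used by the shipped checks

The test suite learns the shared consensus dictionary with 6 folds × 100
iterations and checks replicate properties with 40 stationary replicates
and 5 dynamic replicates; the acceptance script uses 10 folds × 150
iterations for the variance-explained figure and 9 two-group replicates
(18 atom-level corrected p-values) for the weight-decrease figure. These
sizes were chosen so the whole battery runs comfortably on a single CPU;
fold counts beyond ~5 change the consensus dictionary's variance explained
by well under one percentage point on these cohorts, because every fold
sees the same pooled stack and the fits converge long before 150
iterations.

## Known limitations

* The dictionary objective is non-convex; different seeds give different
  local optima. Consensus over folds reduces, but does not remove, this
  variability (per-atom stability quantifies what is left).
* Back-fitted |weight| summaries are not independent across correlated
  atoms; strongly collinear planted states would leak weight into each
  other. The default generator avoids this by design, real data need not.
* The max-t permutation test assumes exchangeability of subjects under the
  null; it is valid for the cross-sectional design and conservative in the
  presence of positive subject effects.
* No atom-number selection is provided: K = 20 is a fixed choice, and
  variance explained necessarily grows with K (monotonicity is tested).
* The high-pass filter is FSL-equivalent in its transfer-function
  behavior, not bit-identical to any particular FSL release.
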