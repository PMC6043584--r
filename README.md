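# dfcstates

Stationary and dynamic functional-connectivity (FC) analysis of
dose-graded anesthesia cohorts in resting-state fMRI, with a seeded
synthetic-cohort generator for end-to-end validation.

## The scientific problem

Increasing the dose of a volatile anesthetic such as isoflurane changes
mouse brain networks in two characteristic ways:

1. **Stationary effect** — the full-scan correlation between *homotopic*
   regions (left/right mirror counterparts of the same area) weakens with
   dose.
2. **Dynamic effect** — decomposing sliding-window connectivity into
   *dynamic functional states* (dFS) shows the weight of states with
   modular network structure falling with dose, while a spatially
   unstructured state of widespread uniform correlation comes to dominate.

`dfcstates` implements the full analysis chain needed to measure both
effects, plus group inference, plus a generator of realistic synthetic
cohorts with exported ground truth so every stage has a recoverable
target.

## The methods at the core

* **Stationary FC** — Pearson and ridge-regularised partial correlation
  networks r, Fisher z = atanh(r), module-ordered matrices, homotopic-edge
  extraction; group inference by unpaired t per edge with *max-statistic
  permutation* correction (null of max |t| over all edges under subject
  relabelling), one-way ANOVA across doses, Benjamini–Hochberg FDR, and
  average-linkage dendrograms under d = 1 − |r|.
* **Dynamic FC** — sliding-window correlations (window 40 TR, step 1 TR)
  vectorised over edges; *sparse dictionary learning* of K = 20
  unit-energy atoms by alternating ℓ1 sparse coding and unit-ball
  dictionary updates, minimising
  ½‖X − DᵀA‖²_F + λ‖A‖₁ with a monotone objective; robustness by many
  folds matched with the *Hungarian algorithm* (|spatial correlation| as
  similarity, sign flips resolved) and averaged into a consensus; *least
  squares back-fitting* of atom weights per window; per-atom summaries
  (mean |weight|) compared between dose groups with t-tests and BH-FDR at
  a fixed atom ordering.
* **Synthetic cohorts** — six latent correlation states (four modular, one
  homotopic, one unstructured) switching with geometric dwell times; dose
  lowers homotopic coupling and shifts state occupancy toward the
  unstructured state; fully seeded, ground truth exported.

## Worked example

A compact two-dose cohort (6 subjects per dose), the stationary homotopic
effect, and the dynamic state analysis:

```r
library(dfcstates)

atlas <- buildAtlas()
atlas
#> ModuleAtlas with 24 regions, 12 homotopic pairs
#> modules: LCN(6), ACN(4), PFN(4), SuCN(6), ThN(4)

cohort <- simulateCohort(cohortConfig(nSubjects = 6L, doses = c(1.1, 2.0),
                                      seed = 42L))
pre <- lapply(cohort$subjects, function(ts)
  varianceNormalize(highpassFilter(ts)))
doseOf <- vapply(pre, dose, numeric(1))

# stationary: mean homotopic Fisher z per dose
vapply(c(1.1, 2), function(d)
  mean(vapply(pre[doseOf == d], function(ts)
    mean(homotopicEdges(fisherZ(fullCorrelation(ts)), atlas)),
    numeric(1))), numeric(1))
#>   1.1     2
#> 0.363 0.282          # homotopic connectivity drops at the high dose

# dynamic: consensus dictionary, variance explained, state recovery
stacks <- lapply(pre, slidingWindowFC, windowLength = 40L, step = 1L)
pooled <- poolStacks(stacks)
dict <- learnConsensusDictionary(pooled, K = 20L, folds = 3L,
                                 nIter = 60L, seed = 42L)
varianceExplained(dict, pooled)
#> 0.601                # 20 atoms explain 60% of the window-stack variance

stateRecovery(dict, lapply(cohort$states, function(s) s@covariance))
#>   state atom    cosine
#> 1     1   11 0.9041008   # every planted state has a matching atom
#> 2     2    1 0.9463128
#> ...

# dose effect on state weights (atom 1 = a planted modular state,
# mean |weight| 0.85 at 1.1% vs 0.35 at 2.0%, q = 4e-4)
wts <- lapply(stacks, function(s) backfitWeights(dict, s))
cw <- compareWeights(summaryMatrix(wts[doseOf == 1.1]),
                     summaryMatrix(wts[doseOf == 2.0]))
subset(cw, q_fdr < 0.01)
#>   atom     meanA     meanB        t            p        q_fdr
#> 1    1 0.8549003 0.3543602 7.014426 3.651549e-05 3.651549e-04
#> 8    8 0.5807588 0.1713733 9.763937 1.977784e-06 3.955568e-05
```

Interpretation: the mean homotopic z falls from 0.36 to 0.28 between the
lowest and highest dose; the consensus dictionary recovers all six planted
states (|cosine| ≥ 0.85); atoms matched to modular states lose weight at
the high dose at stringent FDR levels, while atoms aligned with the
unstructured state (negative t above) gain weight.

The whole pipeline, including per-stage CSV/JSON outputs, a manifest with
checksums and a markdown report, runs as

```r
runPipeline("results/run1", seed = 1L)   # simulates the default cohort
```

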