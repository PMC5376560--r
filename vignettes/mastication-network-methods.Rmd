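---
title: "Methods: masticatory performance and weighted connectivity networks"
author: "masticNet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: masticatory performance and weighted connectivity networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(masticNet)
```

## The scientific question

Masticatory (chewing) performance declines with age, and part of that
decline appears to reflect the brain's intrinsic organisation rather than
purely peripheral oral factors. The analysis implemented here asks: across
a cohort of adults, which nodes of a mastication-related brain network
carry connectivity that tracks individual masticatory performance, after
age and gender are controlled for — and does that set of "hubs" differ
between older and younger adults?

Masticatory performance is scored behaviorally as the **masticatory
performance index (MPI)**: the subject chews a color-changeable gum for
three minutes and the color change of the flattened bolus is measured as
the CIE76 distance in L\*a\*b\* space, `computeDeltaE()`. The brain side
is a resting-state fMRI network over **24 nodes** — 12 bilateral regions
spanning sensorimotor cortex (M1, PMC, S1, S2), parietal and insular
cortex (SPL, aINS), cingulate (dACC), subcortex (CaN, THA) and three
cerebellar subdivisions (CAnt, CPost67, CPost8); see
`masticationNodeLabels()`.

## The model and the statistic

For each subject, regional mean time series are preprocessed and the
**functional connectivity** between every node pair is the Pearson
correlation $r_{ij}$ of their series. Each correlation is converted to an
edge weight by the absolute Fisher transform,

$$ w_{ij} \;=\; \left| \operatorname{atanh}(r_{ij}) \right|
   \;=\; \left| \tfrac12 \log \tfrac{1+r_{ij}}{1-r_{ij}} \right|, $$

giving an undirected, weighted, complete network of $24 \times 23 / 2 =
276$ unique edges (`computeConnectivity()`, `fisherZWeight()`). The
**degree centrality** of node $k$ is the sum of its 23 incident edge
weights (`degreeCentrality()`); a node whose DC is *positively* associated
with the MPI is a mastication-related hub.

The association statistic is the **partial correlation** controlling for
age and gender: both the network quantity and the MPI are residualized by
OLS on an intercept, age and a 0/1 gender indicator (F = 0, M = 1), and
the Pearson correlation $r_p$ of the residuals is tested with
$t = r_p \sqrt{df/(1-r_p^2)}$, $df = n - 2 - k$ (`partialCorrelation()`).
Hub identification (`identifyHubs()`) flags nodes with $r_p > 0$ and
two-tailed $p < 0.05$; edge screening (`screenEdges()`) reports the signed
$r_p$ for all 276 edges and flags $p < 0.05$ **without multiple-testing
adjustment** — the screening is explicitly exploratory, and that choice is
preserved rather than "improved". Group analyses are run strictly within
the older and younger halves of a median split by age
(`medianSplit()`; ties at the threshold are a hard error, never broken
silently); no direct between-group connectivity contrast is computed,
because group differences in anatomy and head motion would confound it.

Two conventions here are documented choices where the original description
is silent: hub p-values are two-tailed with a positivity filter on
$r_p$ (keeping p-values comparable to two-tailed reporting), and gender
enters as a 0/1 indicator.

## Preprocessing

The pipeline applies, in a fixed and enforced order
(`preprocessSeries()`):

1. **Discard** the first 3 of 183 volumes (magnetic saturation), leaving
   180 at TR = 2 s.
2. **Detrend**: least-squares removal of a per-node linear trend.
3. **Bandpass 0.01–0.08 Hz**: an ideal rectangular filter on the discrete
   Fourier transform — coefficients inside the band (boundaries inclusive)
   are kept, all others zeroed. This matches the behavior of the standard
   resting-state toolkits, is exactly testable (unit in-band transfer and
   zero out-of-band transfer at on-grid frequencies), and is idempotent.
4. **Nuisance regression**: OLS residualization on the six motion
   parameters plus mean ventricle and deep-white-matter signals. The
   whole-brain global signal is deliberately *not* regressed. Regressors
   are used as supplied by default; `filterNuisance = TRUE` optionally
   bandpasses them first (whether the original toolchain did so is
   unknowable from the description, so it is a switch, default off).

Applying a stage after a later one (e.g. detrending a filtered series) is
an error: the order is part of the method. Slice-timing correction,
realignment and spatial normalization are out of scope — motion
parameters arrive precomputed, and ROI series are either supplied directly
or extracted from labelled volumes by unweighted voxel averaging
(`extractROITimeSeries()`). Probabilistic atlas maps are binarized at a
group threshold of 0.5 with an inclusive boundary
(`thresholdProbabilisticMap()`).

## Motion quality control

Head motion is summarized per subject as the **mean displacement**: for
each frame, the Euclidean norm of the change in the three translations
(mm) and, separately, the three rotations (degrees), averaged over frames
(`meanDisplacement()`). The displacement convention — vector norms rather
than per-axis averages, rotations kept in degrees — is the simplest
faithful reading of "displacement relative to the previous time point" and
is stated here prominently because other conventions exist. Subjects are
excluded when the *maximal* frame-to-frame displacement reaches 1.5 mm or
1.5°; the boundary is strict (exactly 1.5 fails), reading "< 1.5 mm"
literally. Group motion is compared by a two-tailed two-sample t test
(`compareGroupMotion()`).

## The synthetic cohort generator

No subject-level MRI is available, so the package ships a generator whose
defaults *are* the study conditions: `CohortSpec()` defaults to 183
volumes at TR = 2 s, 24 nodes, a 26/26 older (55–74 y) / younger (23–54 y)
cohort, gender drawn with P(male) = 19/52, an MPI baseline of 73.3 ΔE
units, an age slope of −0.25 ΔE/year within the older group (so that the
older group's mean and its negative age–MPI correlation land near the
published demographics), and behavioral noise SD 1.5 ΔE.

The BOLD stand-in is deliberately the simplest process with controllable
cross- and autocorrelation: Gaussian AR(1) innovations with stationary
unit variance, colored by the symmetric square root of a target
correlation matrix. The default design (`defaultCovarianceDesign()`) is a
qualitative block structure — sensorimotor block, cerebellar block,
subcortical block, cortico-cerebellar cross-links, strong homotopic pairs
— whose numeric values are free parameters, never claims about real data.
The default lag-1 autocorrelation of 0.4 puts most signal power at low
frequencies, as BOLD at TR = 2 s does. Motion traces are cumulative
Gaussian random walks with per-frame step SD 0.02 mm / 0.02° — small
enough that no default subject trips the 1.5 mm/° exclusion, as in the
original cohort where all subjects passed.

**Planted couplings.** The generator builds each subject's MPI as
`intercept + Σ coefficient × realized quantity + age trend + noise`,
where a realized quantity is the subject's degree centrality of a named
node or the weight of a named edge, computed from the **band-limited
(0.01–0.08 Hz) component** of that subject's simulated series. Coupling
behavior to the intrinsic low-frequency connectivity — the quantity the
pipeline estimates — is the design choice here: it makes recovery tests
meaningful end to end (simulate → preprocess → network → statistics)
rather than dependent on broadband sampling noise that preprocessing
removes. All planted quantities are returned in a ground-truth record.

What the generator does **not** emulate: hemodynamic response shaping,
cardiac/respiratory physiological noise, scanner drift and spike
artifacts, spatial autocorrelation between neighboring ROIs, and
between-subject variation in the true correlation design (all subjects
share one design; inter-subject DC variation is sampling variation).
Passing recovery tests therefore demonstrates that the *estimators and
decision rules* behave correctly under a known truth — not that the
pipeline is robust to every artifact of real acquisitions.

## Numerical choices and degenerate inputs

- Perfect correlations (|r| = 1) between distinct nodes are a hard error
  by default — they cannot arise from genuinely noisy data — with an
  explicit `clip` option at `1 − 1e−7` for pipelines that prefer a large
  finite weight. The pipeline runner enables clipping.
- Covariance designs are validated as symmetric, unit-diagonal and
  positive semidefinite with an eigenvalue tolerance of −1e−10; offending
  eigenvalues are reported.
- Constant nuisance regressors are absorbed by the intercept (a single
  constant regressor reduces the regression to demeaning); any remaining
  collinearity is an error naming the column.
- Residual-variance degeneracy in partial correlation (a constant or
  fully-explained variable) is detected relative to the variable's own
  scale.
- The chi-square continuity correction clamps `|O − E| − 0.5` at zero, so
  a perfectly balanced 2×2 table yields exactly 0; this reproduces the
  published gender statistic χ²(1) = 1.33 exactly. The default two-sample
  t mode is Welch, since the published group SDs differ by a factor of
  two; the pooled mode is provided and both reproduce the published
  p-bounds.

## Problem sizes used in the test suite

The suite exercises covariance recovery at 5,000 timepoints (elementwise
sample-vs-design error below 0.06), null false-positive calibration and
planted-coupling recovery on 200-subject cohorts at a fixed seed, and the
end-to-end demo on the 52-subject default cohort — sizes chosen so every
Monte-Carlo bound is comfortably assertable while the whole suite stays
quick on a laptop.

## A worked demo

```{r demo, eval = FALSE}
spec <- CohortSpec(nSubjects = 52, seed = 7,
                   couplingPlan = list(list(target = "CAnt_L",
                                            coefficient = 1.5)),
                   behaviorNoiseSd = 0.3)
report <- runPipeline(pipelineConfig(cohort = spec))
report$demographics$table
report$hubTables$younger
```

## Known limitations

Beyond the generator's simplifications listed above: the ΔE computation
supports only the CIE76 form (the colorimetric variant used for the gum
assay is not further specified anywhere authoritative); edge screening
inherits the original analysis's uncorrected alpha, so its false-positive
burden at 276 tests is by design; and the published per-node hub
statistics from the original cohort are not reproducible without the
subject-level MRI, which is why acceptance here rests on desk-scale
statistics plus synthetic parameter recovery. One published hub entry
(right SPL, "r = 0.48, p = 0.14") is internally inconsistent with its
designation as significant and is treated as a likely misprint, not a
target.
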