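---
title: "Respiration-based sleep staging: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Respiration-based sleep staging: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(respstage)
```

## The problem

Breathing changes systematically with sleep depth. Relative to quiet
wakefulness, non-REM sleep (stages N1 to N3) slows and shallows the breath
as parasympathetic tone rises; REM sleep speeds breathing back up and makes
it irregular. A wearable respiration sensor — here a mask-type triboelectric
generator whose film moves with nasal airflow, producing an open-circuit
voltage pulse per breath — therefore carries enough information to stage
sleep coarsely without EEG. `respstage` implements that idea end to end:
per 30-second window it extracts two features, the **respiration rate**
(breaths/minute, from the dominant spectral frequency) and the **output
voltage** (mean per-breath peak height), scales them, and assigns one of
the five stages `AWAKE, N1, N2, N3, REM` by the nearest of five labeled
centroids in the feature plane.

## The classification model

A window's features $(r, v)$ are mapped to the classification plane by two
steps:

* **relative output voltage** $y = v / v_{\max}$, where $v_{\max}$ is the
  largest voltage in the *training* data. Dividing by the training maximum
  suppresses day-to-day drift of the absolute output (electrode wear,
  humidity, mask fit) that would otherwise dominate the distance. The
  reference is stored in the fitted model and reused unchanged on new
  data, so held-out windows may legitimately map above 1.
* **rate weighting** $x = W \cdot r$ with default $W = 0.1$. Raw rates
  (≈ 12–18) are an order of magnitude larger than relative voltages
  (≤ 1), so without $W$ the Euclidean distance would be decided by the
  rate alone. $W = 0.1$ brings the two axes to a similar order.

A point $(a, b)$ is assigned to the stage of the centroid $(x_i, y_i)$
minimising

$$D_i = \sqrt{(x_i - a)^2 + (y_i - b)^2},$$

with exact ties going to the lowest centroid index. With rate 17.5 and
output 3.5 V against centroids $A = (17.5, 0)$ and $B = (13.5, 1)$ this
gives $D_A = 3.5$ and $D_B = 4.72$, so the window joins cluster A — the
package's `stage_distance()` and `classify()` reproduce this example
exactly, and it anchors the unit tests.

Note what is *not* an invariance: scaling only the rate axis changes the
decision boundaries — that is the entire point of sweeping $W$. The true
equivariances of the distance (common rescaling of both axes, translation)
are property-tested instead.

### Fitting the centroids

`stage_fit()` supports two centroid constructions:

* **`mode = "kmeans"`** (the default): unsupervised Lloyd k-means with
  $k = 5$, implemented in the package with a seeded greedy farthest-point
  initialisation, `n_init = 10` restarts scored by within-cluster sum of
  squares, convergence tolerance `1e-6`, at most 300 iterations, and
  empty clusters reseeded at the point farthest from its assigned
  centroid. The per-iteration objective trace is retained and asserted
  non-increasing in the tests; `stats::kmeans` serves as an independent
  cross-check on well-separated data. Clusters are then labeled by
  majority vote over the training labels (`label_centroids()`); `"strict"`
  labelling refuses ties and duplicated stages, `"lenient"` resolves them
  greedily by largest count, then lowest cluster index.
* **`mode = "supervised"`**: one centroid at each stage's mean of the
  labeled training features ("featured-data" centroids). Because cluster
  means are linear, these centroids commute exactly with the scaling map.

The weight sweep (`weight_sweep()`) uses supervised centroids by default:
as $W \to 0$ the plane collapses onto the voltage axis and k-means refits
become unstable local optima, whereas stage-mean centroids converge
smoothly to the voltage-only classifier, producing the characteristic
sweep shape — accuracy rising to an interior optimum near $W = 0.1$, then
declining and flattening once the rate no longer contributes.

### Evaluation conventions

`evaluate()` tallies a 5×5 confusion matrix over aligned windows;
per-stage accuracy is the diagonal over the row sum, and the **averaged
accuracy is the unweighted mean of the five per-stage accuracies** (the
convention under which per-stage accuracies of 89.17, 86.67, 88.33, 87.50
and 84.17 % average to 87.17 %). The benchmark split is stratified with
equal windows per stage (default 40 train + 40 test), seeded.

## The synthetic-data generator

No public recordings exist for this sensor class, so the package ships a
first-class generator whose defaults define the study conditions.

**Breath waveform.** One breath is a trapezoid pulse: linear rise while
the film approaches and contacts the electrode during exhalation, a
plateau at the breath amplitude while contact holds, and a linear fall
back to 0 V during inhalation, with default phase fractions
(0.25, 0.25, 0.50) of the period. Cycles are laid out in continuous time
(onset times accumulated breath by breath, the waveform evaluated at the
sample instants) so planted frequencies are exact rather than quantised
to the 0.017 s sample grid.

**Stage models.** Each stage has an epoch-level breath frequency draw
$f_0 \sim N(\mu_f, \sigma_f)$ truncated to (0.05, 1] Hz and an epoch-level
amplitude draw, with per-breath jitter applied multiplicatively through
the coefficients of variation `breath_period_cv` and `breath_amp_cv`. The
epoch-level/per-breath split matters: per-breath jitter averages out
within a 30-s window, so only the epoch-level spread produces the
across-window rate dispersion that makes REM hard to classify. Defaults
(`default_stage_models()`):

| stage | $\mu_f$ (Hz) | $\sigma_f$ (Hz) | amp mean (V) | amp sd (V) | period cv | amp cv |
|-------|------|-------|------|------|------|------|
| AWAKE | 0.272 | 0.006 | 7.89 | 0.25 | 0.03 | 0.05 |
| N1    | 0.264 | 0.005 | 7.10 | 0.22 | 0.03 | 0.05 |
| N2    | 0.233 | 0.005 | 6.31 | 0.20 | 0.02 | 0.04 |
| N3    | 0.210 | 0.004 | 5.52 | 0.17 | 0.02 | 0.04 |
| REM   | 0.292 | 0.015 | 7.89 | 0.70 | 0.12 | 0.15 |

The frequency means are the observed per-stage dominant frequencies for
this sensor class; 7.89 V is the normal nasal-breath output, and the
(1.0, 0.9, 0.8, 0.7) amplitude ladder encodes the qualitative weakening
of airflow through the non-REM depths. The dispersion columns are the
package's own synthetic choices, fixed once on physiological grounds —
breathing grows more regular with non-REM depth, REM is markedly
irregular (about 3× the awake variability) — and are *not* measured
values. They are overridable per field through the YAML configuration.

**Acquisition artifacts.** A constant DC offset (default 2.5 V, the
mid-rail bias of a 5 V acquisition board) plus white Gaussian noise
(default sd 0.05 V) are added per sample; preprocessing removes the
offset by subtracting the window **median**, which resists the asymmetry
of the breath waveform better than the mean. Snoring epochs attenuate the
breath amplitude and multiply a high-frequency vibration (default 8 Hz,
depth 0.5) onto the exhalation segments.

**What the generator does not emulate.** Motion and mask-shift artifacts,
apnea, gradual drift within a night, inter-participant differences,
humidity and head-angle effects, and any EEG ground-truth uncertainty —
stage labels are exact by construction. Passing benchmarks on this
generator therefore demonstrates the correctness and calibration of the
pipeline under its stated signal model, not clinical performance on real
nights.

## Numerical choices

* **Spectral grid.** 30 s windows have a raw resolution of ≈ 0.033 Hz;
  the transform is zero-padded to a power of two giving a grid spacing of
  at most 0.002 Hz, so dominant frequencies are reported to three
  decimals deterministically. No taper is applied by default (the
  fundamental dominates the trapezoid's spectrum comfortably); a taper
  function can be supplied.
* **Windowing.** Consecutive non-overlapping windows; a trailing
  remainder shorter than half a window is dropped, otherwise kept. A
  window's stage label is the epoch containing its midpoint. Note
  30 s is not an integer multiple of 0.017 s: a window is
  `round(30/0.017) = 1765` samples, i.e. 30.005 s.
* **Peak detection.** Positive local maxima with topographic prominence
  ≥ 20 % of the window's maximum absolute value, greedily thinned to a
  minimum separation of $0.5/f_{hi}$ seconds (1 s for the default band),
  summarised by the mean height (max available via configuration).
* **Determinism.** Every stochastic operation takes an explicit seed and
  restores the caller's RNG state; sessions derive epoch seeds as
  `seed + epoch index`. Model files serialise doubles with 17 significant
  digits, so save/load round-trips are bit-stable, and every output file
  is stamped with the MD5 hash of the producing configuration.

## Benchmark sizes and known limitations

The default benchmark simulates (40 + 40) × 5 = 400 thirty-second windows
(about 3.3 h of signal), chosen to mirror the 40-windows-per-stage design
of the original experiment while keeping a full pipeline run in a few
seconds; the tests use the same scale.

Known limitations worth stating plainly:

* With the default geometry the REM cloud deliberately overlaps AWAKE
  (same amplitude, higher but widely dispersed rate), so REM is the
  worst-classified stage — as observed on real data. A consequence is
  that unsupervised k-means clusters need not align with stages: under
  unlucky seeds the k-means fit can split the REM cloud and merge
  neighbours, and lenient labelling then degrades accuracy substantially.
  The supervised centroid mode does not have this failure mode; for
  deployment-like use we recommend it whenever labeled training windows
  exist.
* The nearest-centroid rule uses an isotropic distance and is blind to
  the very different per-stage dispersions; a variance-aware rule would
  classify REM better but is deliberately out of scope.
* Windows are classified independently; no temporal smoothing of the
  hypnogram is applied.
* The 0.017 s sampling interval gives 1765 samples per 30 s window; the
  commonly quoted "approximately 1800" is a rounding of the same setup,
  and the package follows the exact arithmetic.

## A worked run

```{r, eval = FALSE}
res <- run_pipeline(seed = 1)
res$report           # confusion matrix, per-stage and averaged accuracy
res$sweep            # averaged accuracy per candidate weight
plot(res$fit, res$features[res$split$train, ])
```
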