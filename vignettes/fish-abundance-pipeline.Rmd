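---
title: "Counting fish in fixed-camera image sequences: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting fish in fixed-camera image sequences: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Cabled underwater observatories photograph the same scene for months at a
fixed interval (typically every 30 minutes), day and night. Turning those
images into a fish abundance time series by eye is expensive; doing it
automatically is hard because the scene itself keeps changing: daylight
gives way to vignetted artificial light, turbidity blurs and flattens the
image, and bio-fouling slowly grows over the camera porthole. `fishcam`
implements a recognition pipeline built around one structural assumption:

> In a time-sorted fixed-camera sequence, the relevant subjects (fish) change
> between consecutive frames faster than the irrelevant content (background,
> fouling).

Everything static is therefore removed by differencing consecutive frames,
and only the moving remainder is ever classified.

## Segmentation

For frame $t$ the pipeline computes $D_t = |I_t - I_{t-1}|$, the per-pixel
absolute difference against the previous frame. The absolute value means
both the arrival position and the departure position ("ghost") of a fish
produce blobs; ghosts fall into the negative class naturally and are
rejected by the classifier rather than by an extra heuristic.

$D_t$ is Gaussian-blurred (kernel `k_blur = 5` px, `sigma_blur = 1.5`),
thresholded against a locally adaptive surface — the Gaussian-weighted
neighbourhood mean over a `block = 51` px window plus an `offset = 7`
(intensity units on the 0–255 scale) — and cleaned by morphological opening
then closing with a 5 px elliptical kernel. Connected components smaller
than `min_blob_area = 100` px are dropped. These defaults are standard
small-moving-object values; every one of them is a `seg_params()` argument.
The local (rather than global) threshold is what keeps the segmentation
usable across day/night illumination and turbidity-compressed contrast.

Fish bodies reflect light unevenly, so difference blobs have jagged,
partial silhouettes. Each surviving component is therefore characterised by
the *convex hull* of its pixels; the hull's bounding box is mapped back
onto the original frame and the grayscale crop becomes the region of
interest (RoI). Components touching the border are kept — a half-visible
fish is still a fish. Overlapping RoIs are all kept: a school split into
several regions still carries the magnitude of the abundance, which is what
the downstream correlation analysis consumes.

## Features

Each RoI is described by a fixed 22-feature schema: nine texture features of
the patch (intensity mean, population SD, skewness, kurtosis, 256-bin
Shannon entropy, and the four co-occurrence statistics contrast,
correlation, energy, homogeneity, computed on a 32-level quantisation at
distance 1 and averaged over the 0°/45°/90°/135° offsets) and thirteen
shape features of the hull and component mask (hull area and perimeter,
circularity $4\pi A/P^2$, bounding-box aspect ratio, solidity, best-fit
ellipse eccentricity, and the seven log-scaled Hu moment invariants).

Two numerical choices matter here. First, the hull pixel area is computed as
the shoelace area of the pixel-centre polygon plus $P/2 + 1$ (a Pick-style
boundary correction), so that a convex component is its own hull with
solidity exactly 1 instead of slightly above it. Second, degenerate
statistics are defined rather than propagated: on a constant patch the
co-occurrence correlation, skewness and kurtosis are 0, entropy is 0 and
energy is 1, so no RoI the segmenter can emit ever produces a non-finite
feature.

The schema is deliberately a *superset*: the evolutionary learner performs
implicit feature selection (features absent from every winning tree are
unselected, and `feature_usage()` reports the per-feature usage frequency),
so the pipeline is robust to the exact feature list. The extractor registry
(`default_feature_extractors()`) can be replaced without touching the
learner. Features are min–max normalised to $[0,1]$ with training-set
ranges stored inside the model; test-time values are clipped to the range.

## The classifier: genetic programming inside balanced repeated CV

The fish/non-fish decision function is an expression tree over the
normalised features, ephemeral constants in $[-1, 1]$, and the operator set
$\{+, -, \times, \div_p, \min, \max, \mathrm{neg}, \mathrm{ifgt}\}$, where
$\div_p$ is protected division (returns 1 on a zero denominator) and
`ifgt(a,b,c,d)` returns $c$ if $a > b$ else $d$. The classifier output is 1
exactly when the raw tree value is positive.

Search is generational GP: ramped half-and-half initialisation (depths
2–6), tournament selection (size 5), depth-limited subtree crossover
(probability 0.8), subtree/point mutation (probability 0.15), elitism 1,
population 200, 30 generations, maximum depth 8 and a 150-node cap (the
4-ary conditional can bloat within a depth limit alone). Fitness is
**balanced accuracy minus a parsimony penalty** of 0.001 per node: the
training design below balances the classes, so plain accuracy would be
acceptable, but balanced accuracy stays meaningful if a user changes the
sampling, and the parsimony term counteracts bloat. All defaults live in
`gp_config()`.

RoI example pools from fixed cameras are heavily imbalanced — few fish
regions against a large background of ghosts, noise blobs and reef edges.
`balanced_cv()` therefore runs a repeated, class-balanced, stratified
k-fold cross-validation: each of the (default 10) repeats draws as many
negatives as there are positives, uniformly without replacement, reshuffles
the positives, forms class-stratified folds (default 10) and trains one GP
run per fold rotation. Confusion counts (and ACC/TPR/FPR) are recorded on
each held-out fold; the summary reports their mean and SD over all
`k × repeats` folds. The repeat's champion — the fold individual with the
best held-out balanced accuracy — joins the final ensemble, which
classifies by majority vote (vote fraction > θ, default θ = 0.5). The
combiner is a plain field of the ensemble object and can be swapped.

Per-fold normalisation ranges are taken from the whole example pool rather
than recomputed per training fold; min–max ranges are order statistics with
negligible fold-to-fold leverage, and a single range set is what ships with
the model.

The per-image count is simply the number of RoIs the ensemble votes
positive. No non-maximum suppression and no crowd handling is applied, by
design: each member of a school that segments separately is counted.

## Time-series evaluation

`build_series()` pairs, per frame, the manual count with the recognised
count (the first frame of a sequence has no difference image and is
excluded). The paired series can be reduced (dropping wrong-PTZ and
corrupted frames, optionally a crowding cutoff — disabled by default since
no principled threshold exists), stratified by turbidity/fouling scores
(0–3 each), and aggregated to three scales: raw 30-min samples, per
(calendar day × photoperiod) means, and calendar-month means. Photoperiod
is day when solar irradiance exceeds 5 W·m⁻² (no standard cutoff exists;
civil twilight irradiance is of this order, and the label is insensitive to
the exact value because irradiance crosses it steeply); calendar boundaries
use the observatory's civil time zone (default CET). Agreement is measured
by Pearson's r with the two-sided p from the t-transform on n−2 df.
Correlations of constant series or fewer than 3 pairs are reported as
*missing*, never as 0 — sparse strata must be visibly undefined, not
deceptively uncorrelated.

## Ecological statistics

Day-vs-night and month contrasts use a univariate permutation PERMANOVA on
the Euclidean resemblance matrix of square-root-transformed abundances:
pseudo-$F$ is the among/within partition of squared distances scaled by
degrees of freedom, and $p = (\#\{F^* \ge F\} + 1)/(n_{perm}+1)$ under free
label permutation (default 9,999 permutations; the permutation scheme and
count are package choices since no canonical values exist). On univariate
Euclidean data pseudo-$F$ is algebraically the one-way ANOVA $F$ — the test
suite asserts this identity against `aov()` and `vegan::adonis2()` rather
than implementing through it. For $n \le 8$ all label permutations are
enumerated and $p$ is exact; pairwise contrasts report
pseudo-$t = \sqrt{F}$ per group pair. A greedy collinearity pre-filter for
covariates drops, while any pair correlates at $|r| \ge 0.70$, the member
of the worst pair with the larger mean absolute correlation (name-order
tie-break), deterministically and independent of column order.

## The synthetic scene generator

Real observatory imagery is not redistributable, so validation runs on a
generator that emulates the acquisition conditions while providing exact
ground truth: a static textured background; fish as intensity-contrasted
ellipses with mild body texture, placed per frame with Poisson counts
(day mean 3, night mean 1 by default — night abundance is substantially
lower in shallow coastal scenes) and displaced by at least one body length
between frames; occasional schools (probability 0.05, Poisson size 6) with
overlapping bodies; bio-fouling as dark, nearly opaque patches anchored at
the frame border, *identical between consecutive frames* except at slow
growth steps (every 50 frames), with score-graded coverage (4/7/10 patches
at radii 0.10/0.13/0.17 of the short frame side, roughly 7 %/18 %/37 % of
the frame); turbidity score $s$ as a whole-frame Gaussian blur
$\sigma = 1.0\,s$ plus contrast scale $1 - 0.15\,s$; day frames uniformly
lit and night frames vignetted; and a small probability (0.02) of a
corrupted noise frame. The manual observer is emulated by counting every
fish at least 20 % visible through the fouling — a human scores partially
occluded fish, while the segmenter increasingly fragments them, which is
exactly the divergence that degrades recognition under fouling.

Fish are ellipses, not fish renders, on purpose: every operator in the
pipeline (differencing, thresholding, hulls, texture/shape statistics, GP)
is exercised identically, and the ground truth is exact. What the generator
does **not** emulate: species morphology and behaviour, light physics,
3-D perspective, fish that linger motionless across frames (these would be
differenced away — a real limitation of the method itself), and gradual
illumination drift within a photoperiod. Passing tests therefore
demonstrate that the pipeline recovers abundance dynamics under the modelled
disturbances; they cannot certify performance on any particular real
camera.

For training on synthetic data, RoIs are auto-labelled positive when the
hull overlaps a true fish with IoU ≥ 0.3 — permissive on purpose, because
partial-fish regions are legitimate positives. The end-to-end validation
trains on sequences spanning the condition grid (turbidity 0–3 crossed
with fouling {0, 2}), the way a year-long training sample spans its
conditions; a classifier trained on clear water only would confound
condition shift with recognition failure.

## Problem sizes and determinism

The shipped tests and the acceptance script run on 120×160 px frames,
sequences of 100–300 frames, feature pools of 400 + 400 examples and the
full default CV (10 repeats × 10 folds); these sizes exercise every code
path at full default hyperparameters while keeping a complete run in the
minutes range. Every stochastic step — scene generation, negative
subsampling, fold assignment, evolution, permutation tests — takes an
explicit integer seed and is bit-reproducible from it; derived sub-seeds
are drawn once from the seeded generator, so repeats and folds are
independent but jointly reproducible.

## Known limitations

- Differencing misses stationary fish and double-detects fast ones (ghost
  regions); the classifier absorbs ghosts only as well as its negatives
  represent them.
- Counts are RoI counts: one region containing several overlapping fish
  undercounts, several regions on one fish overcount. Correlation with
  manual counts, not absolute error, is the supported evaluation.
- The irradiance threshold, YAML-configured like everything else, needs a
  sensor; without one, photoperiod labels must be supplied in the manifest.
- Heavy fouling is a physical occlusion: no classifier choice recovers fish
  behind an opaque patch, so degradation with fouling score is expected and
  monitored rather than eliminated.
- Config files are YAML (`load_run_config()`): the established
  configuration format in the R ecosystem, with nested blocks for the
  segmentation, GP and scene parameter groups and strict unknown-key
  rejection.
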