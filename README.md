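# fishcam

Automated fish abundance estimation from fixed underwater camera image
sequences.

Cabled coastal observatories photograph the same scene every 30 minutes,
day and night, for months. `fishcam` turns such a time-stamped image
series plus an annotation manifest into a fish abundance time series and
evaluates it the way an ecologist would: against manual counts, across
illumination, turbidity and bio-fouling conditions, and through the
standard day/night and seasonal contrasts.

The pipeline, for users who count animals rather than pixels:

1. **Segmentation** — consecutive frames are differenced
   (`|I_t − I_{t−1}|`), so everything static (background, reef, fouling on
   the housing) cancels and only moving subjects survive. The difference is
   blurred, thresholded against a locally adaptive Gaussian-weighted mean,
   morphologically cleaned, and each remaining blob is characterised by the
   **convex hull** of its contour; the hull's bounding box, mapped back to
   the original frame, is a candidate fish region (RoI).
2. **Features** — each RoI is described by 22 texture and shape features
   (intensity statistics, gray-level co-occurrence statistics, hull
   geometry, Hu moment invariants).
3. **Recognition** — a binary fish/non-fish classifier is an ensemble of
   **genetic-programming expression trees**, trained inside a repeated,
   class-balanced, stratified 10-fold cross-validation: each repeat
   subsamples negatives down to the number of positives, and the per-fold
   held-out confusion counts yield ACC = (TP+TN)/(TP+FP+FN+TN),
   TPR = TP/(TP+FN), FPR = FP/(FP+TN). The per-image count is the number
   of RoIs the ensemble votes positive.
4. **Evaluation** — observed and recognised counts are paired per frame,
   optionally reduced (wrong pan-tilt-zoom positions, corrupted frames),
   stratified by turbidity/fouling scores (0–3), aggregated at 30-min,
   day/night and monthly scales, and compared by Pearson correlation and
   by univariate permutation PERMANOVA (pseudo-F on the Euclidean
   resemblance matrix of square-root-transformed abundances).

Because real observatory imagery is not redistributable, the package ships
a fully ground-truthed synthetic scene generator (`generate_sequence()`)
emulating the acquisition conditions — day/night illumination, turbidity
blur and contrast loss, growing near-lens fouling patches, fish schools,
corrupted frames — on which the entire pipeline is validated end to end.

## Worked example

Simulate a small observatory dataset, train the recogniser on its ground
truth, predict counts, and evaluate:

```r
library(fishcam)

cfg <- run_config(seed = 7, cv_k = 5L, cv_repeats = 2L,
                  scene = list(frame_shape = c(120, 160), n_frames = 200,
                               day_mean = 3, turbidity = 1))
dir <- file.path(tempdir(), "obs2013")
cmd_simulate(dir, cfg)
model <- file.path(tempdir(), "model.json")
cmd_train(dir, model, cfg, out_report = file.path(tempdir(), "cv.csv"))
#> examples: 333 positive / 349 negative; CV ACC 0.975
pred <- file.path(tempdir(), "counts.csv")
cmd_predict(dir, model, pred, cfg)
res <- cmd_evaluate(dir, pred, file.path(tempdir(), "eval"), cfg)

subset(res$raw_30min_reduced, n > 0)
#>   turbidity fouling         r            p   n
#> 2         1       0 0.8500408 3.417009e-56 197
res$permanova$observed
#> <permanova> pseudo-F(1,7) = 333.944, p = 0.0082 (sampled, 9999 perms)
res$permanova$recognized
#> <permanova> pseudo-F(1,7) = 55.755, p = 0.0082 (sampled, 9999 perms)
```

Reading the output: the cross-validated classifier separates fish RoIs
from background regions (mean held-out accuracy 0.975 over the 10
validation folds); at 30-min resolution the recognised series tracks the
manual counts at r = 0.85 over 197 paired frames; and both the observed
and the recognised day/night-averaged abundances show the same significant
day-versus-night difference (the day/night contrast survives automation).
`cmd_evaluate()` also writes the full 4×4 turbidity×fouling correlation
grids, per scale and for the complete and reduced datasets, as CSV.

The same commands are available from a shell through the installed
dispatcher:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/fishcam.R", package="fishcam"))')" \
  simulate --out /tmp/obs --seed 7
```

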