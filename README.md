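# sishdetect

Star-convex nuclei detection for HER2-SISH brightfield histology, in R.

In silver-enhanced in situ hybridization (SISH) images of breast
tissue, HER2 amplification is scored by counting black HER2 and red
CEN17 dot signals inside individual nuclei. The step that limits
automation is detecting each nucleus as one object in images full of
touching and overlapping cells. `sishdetect` implements a complete
two-stage detection pipeline for this image class, aimed at method
developers and image-analysis researchers who need a self-contained,
fully testable reference implementation:

1. **Preprocessing** — Macenko stain normalization in optical-density
   space (`OD = -log10(I/255)`; stain vectors from the SVD plane of
   tissue pixels at the α/100−α percentile angles) and foreground
   extraction by combined Otsu + local-mean thresholding with
   morphological cleanup.
2. **Stage-1 pseudo-labels** — a marker-controlled watershed bootstrap
   on the foreground distance transform, filtered and patchified into
   256 px training tiles (the full-scale default; the demo uses
   smaller tiles).
3. **Stage-2 star-convex model** — a compact U-Net predicting, per
   pixel, an object probability and distances to the object boundary
   along `R` radial directions, so each pixel parameterizes a
   star-convex polygon. Training minimizes
   `BCE(prob) + λ · probability-weighted MAE(dist)` with SGD
   (momentum 0.9). Inference thresholds the probability map, prunes
   the candidate polygons by greedy non-maximum suppression on polygon
   IoU, and rasterizes the survivors into an instance mask.
4. **Evaluation** — object-level TP/FP/FN with one-to-one
   maximum-IoU matching (split nuclei count 1 TP + k−1 FP),
   point-annotation matching by containment, an expert-criteria filter
   (≥2 red signals, non-overlapping, non-border-touching), and
   `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`,
   `F1 = 2TP/(2TP+FN+FP)` reported as rounded percentages.

Because clinical SISH slides are not redistributable, the package
includes a seeded synthetic scene generator (star-convex nuclei with
red/black dot signals rendered through a known stain matrix) that
provides exact ground truth for every stage, plus bundled benchmark
TP/FP/FN count tables against which the metric formulas are validated.

## Worked example

```r
library(sishdetect)

# 20 seeded synthetic SISH scenes; train on 16, hold out 4
scenes <- demo_scenes(seed = 2)
fit    <- demo_fit(scenes, seed = 11)     # ~6 min on one CPU

held_out <- scenes[fit$test_idx]
det <- predict_image(held_out[[1]]$image, fit$predictor)
m   <- match_instances(det$instance_mask, held_out[[1]]$mask, 0.5)
detection_metrics(m, "scene017")
#>   image_id gt tp fp fn recall precision   f1
#> 1 scene017  8  7  0  1   87.5       100 93.3

pooled_detection_f1(function(img) predict_image(img, fit$predictor),
                    held_out)$f1
#> [1] 0.8813559
```

The `detection_metrics` row reads: 8 ground-truth nuclei on this
held-out scene, 7 detected (one member of an overlapping pair was
missed), no spurious detections — recall 87.5%, precision 100%,
F1 93.3%. The pooled value aggregates TP/FP/FN over all four held-out
scenes before forming F1 (here 0.881: 26 of 32 nuclei matched, one
false positive). Forty percent of the nuclei overlap a neighbour —
the regime in which the star-convex model outperforms the
marker-controlled watershed baseline (pooled F1 0.814 on the same
scenes).

A full end-to-end run (synthesis → normalization → foreground →
pseudo-labels → patches → training → prediction → evaluation, with a
hashed artifact manifest):

```r
run_pipeline(pipeline_config(seed = 1), "run1")
```

A thin command-line front end with the same stages as subcommands is
installed at `inst/cli/sishdetect.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/sishdetect.R", package="sishdetect"))')" synth --out scene/
```

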