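---
title: "Star-convex nuclei detection for HER2-SISH images: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Star-convex nuclei detection for HER2-SISH images: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sishdetect)
```

## The problem

Silver-enhanced in situ hybridization (SISH) stains breast-tissue
sections so that HER2 gene copies appear as black dots and chromosome-17
centromere (CEN17) probes as red dots inside bluish-purple nuclei.
HER2 amplification status is scored as a ratio of these signals counted
inside individual nuclei, so reliable, automated *nucleus detection* —
one object per nucleus, robust to touching and overlapping cells — is
the bottleneck step. `sishdetect` implements a two-stage detection
pipeline for such brightfield images: classical preprocessing and a
bootstrap segmenter produce pseudo-labels, and a compact trainable
star-convex polygon model is then fitted and evaluated at object level.

Clinical SISH slides are not redistributable, so the package ships a
seeded synthetic scene generator that emulates the image class and
provides exact ground truth; every claim the test suite makes is backed
by quantities computed on those scenes.

## Synthetic scenes

`generate_scene()` places star-convex nuclei by rejection sampling:
configurable fractions overlap a neighbour or touch the image border,
and the rest are well separated. Nucleus outlines are smooth radial
functions `r(theta) = r0 (1 + a s(theta))` with a low-order harmonic
perturbation `s`, so every outline is star-convex by construction.
Contested pixels go to the later-placed nucleus (a label image must be
a partition); the `overlaps_neighbor` flag is computed from the
pre-resolution geometry. Red (CEN17) and black (HER2) signals are
painted as 1–2 px disks inside nuclei.

Rendering goes through the Beer–Lambert model: two concentration maps
(nuclear counterstain; red signal stain) are combined through a 3×2
unit-column stain matrix in optical-density space, inverted to
intensities, and corrupted with Gaussian noise. Black dots are rendered
as a heavy *mixture* of both stains: this keeps every pixel's OD inside
the two-stain span so the stain basis remains identifiable. Dot
concentrations (1.1 per stain for black, 0.9–1.2 for red) are chosen
so dot pixels stay inside the 0–255 dynamic range — saturated
intensities would censor the OD and bias concentration estimates.
The defaults (background intensity 235, nuclei levels 0.55–0.95,
noise sd 2–3) give scenes with the qualitative anatomy of SISH ROIs:
pale tissue, dark bluish-purple nuclei, sparse dark dots.

What the generator does *not* emulate: chromatin texture, scanner
optics, focus gradients, tissue folds, and the long-tailed size and
density statistics of real ROIs. Passing tests therefore demonstrate
the correctness and internal consistency of the pipeline, not clinical
performance.

## Stain normalization

`estimate_stain_profile()` implements Macenko's method: convert RGB to
optical density with `OD = -log10(I / 255)`, discard pixels with any
channel below the transparency threshold `beta = 0.15`, project the
remaining pixels onto the top-2 singular plane, and take the `alpha`
and `100 - alpha` percentile angles (`alpha = 1`) as the two stain
directions. These are the reference method's canonical parameter
values. Two conventions make the result deterministic: stain vectors
are sign-flipped to non-negative orientation, and the column with the
larger red-channel OD component is stain 1.

Robust per-stain maximum concentrations are the 99th percentiles of the
least-squares unmixing *over the beta-retained tissue pixels*. Using
all pixels instead makes the percentile depend mostly on how much pale
background a scene happens to contain, which destroys comparability
between a source image and the reference.

`normalize_to_reference()` unmixes against the source profile
(ordinary least squares with zero-clipping — at two stains a
non-negativity solver changes almost nothing), rescales each
concentration map by the reference/source maximum ratio, and recomposes
through the reference vectors. Zero-clipping perturbs the small
fraction of pixels whose OD falls slightly outside the estimated stain
cone (the percentile selection puts the vectors just inside the true
extremes); the identity transform is therefore exact to ±2 intensity
steps for ~99% of pixels rather than all of them.

The reference profile shipped in `inst/extdata/` is estimated from a
canonical seeded synthetic scene (it is synthetic, not derived from any
clinical image) and is the fixed normalization target throughout.

Validation renders a *stain-shifted twin* of each scene — same
geometry, hue rotated by −12° and per-stain strengths scaled by
(0.8, 1.3) — and checks that normalization brings the re-estimated
profile within 5° of the reference and raises SSIM against the
reference rendering. Two design notes: the rotation is negative
because a positive rotation pushes the red stain's R-channel OD below
`beta`, a degenerate configuration in which Macenko's filter discards
exactly the pixels that define that stain; and the strength scaling is
per-stain because grayscale SSIM is almost invariant to a single global
scale (that is what its luminance/contrast normalization is designed
to ignore).

`ssim()` is the standard windowed form with `C1 = (0.01 L)^2`,
`C2 = (0.03 L)^2` and a 7×7 uniform window, averaged over fully
interior window positions.

## Foreground extraction

Luminance (Rec. 601 weights) is histogram-equalized to the full 0–255
range, then foreground = (below global Otsu threshold) OR (below local
51-px mean minus 10), followed by a disk-opening of radius 2 and
filling of interior holes smaller than 20 px. Nuclei are darker than
background throughout, which fixes the inequality directions. The
grayscale-then-equalize order and the specific local rule are design
choices; equalization's rank preservation makes the mask invariant to
constant intensity offsets.

## Star-convex geometry

Ground truth for training follows the star-convex representation: for
each foreground pixel, distances to the instance boundary along
`n_rays` equally spaced rays, plus an object probability defined as the
per-instance boundary EDT normalized to max 1 (so centers are
prioritized both in the loss weighting and in candidate selection).

Radial distances are measured by marching along each ray in
quarter-pixel steps and recording the last sample whose nearest pixel
still belongs to the instance. Whole-pixel stepping was evaluated
first and rejected: rounding the sampled trajectory makes it exit up to
~1.2 px early on diagonal directions, and no constant rasterization
offset can then reconstruct a radius-5 disk to IoU ≥ 0.95. With
quarter-pixel sampling and the matching half-sample (0.125 px)
coverage rule in the rasterizer, disks of radius 5–20 reconstruct from
their center-pixel polygon at 32 rays with IoU ≥ 0.96.

Polygon IoU is pixel-set intersection over union on the integer grid;
greedy NMS processes candidates by descending score (ties broken
lexicographically by center for determinism) and keeps a candidate iff
its IoU with every kept candidate is below the threshold. Kept
polygons are painted in ascending-score order so higher-score polygons
win contested pixels — the overlap-resolution convention of this
package.

## The predictor and its training

The predictor is a compact U-Net: `depth` pooling stages of two 3×3
convolutions each, nearest-neighbour upsampling with skip
concatenation, a sigmoid head for object probability and a softplus
head for the `n_rays` distances. Inputs are percentile-normalized
(1st–99th) to [0, 1]. The default architecture (depth 2, 8 base
filters, 16 rays for the demo configuration) is deliberately far
smaller than production nuclei models: the package's contract is that
the full pipeline trains and validates on a desk-scale CPU budget, and
the synthetic scenes are simple enough for a small network.

The loss is `BCE(prob) + lambda * weighted-MAE(dist)` with
`lambda = 0.2` (keeps both terms the same order of magnitude at
initialization). The distance term weights each pixel by the target
object probability and normalizes by the total weight, so background
pixels contribute nothing and center pixels dominate. The probability
target is the soft EDT-based map by default (`prob_target = "binary"`
gives the 0/1 variant): the soft target is what makes center pixels
score highest, which greedy NMS depends on to select well-centered
polygons.

Optimization is SGD with momentum 0.9 and an 80:20 train–validation
split; the returned parameters are those of the best validation epoch.
Augmentation draws a k·90° rotation and independent flips per patch
per epoch, and the radial targets are recomputed from the transformed
mask (under these exact symmetries the targets permute exactly; no
interpolation is involved). Two initialization details matter for
stable small-scale training: the probability head bias starts at −2
(the background prior) and the distance head bias at softplus⁻¹(3)
(a typical in-object radius); the learning rate is multiplied by 0.2
over the final 30% of epochs. Without these, runs on some seeds stall
in a regime where the probability map plateaus near the threshold and
fragments survive NMS.

After training, `optimize_thresholds()` sweeps the candidate
probability threshold (and optionally the NMS IoU threshold) on the
validation patches and stores the best pair in the predictor — the
standard final step for this model family; the fixed defaults
(0.5 / 0.4) remain when no optimization is run.

The "accuracy" recorded per epoch is `1 −` pixel error of the
thresholded probability map; it is reported for curve inspection only.

The single-patch memorization check (training until the patch's own
nuclei are recovered with F1 = 1) is run with a few seeded restarts:
the fit is nonconvex and a minority of initializations stall in a
flat regime at this scale; the property of interest is that the
procedure can memorize, not that every initialization does.

## Pseudo-labels and the watershed baseline

Stage 1 produces training labels without a pretrained network:
`watershed_baseline()` computes the foreground EDT, places markers at
its local maxima with a minimum separation `h = 7` px, and grows
marker regions on the negated distance map restricted to the
foreground. `pseudo_label()` wraps any segmenter, discards instances
whose pixel majority lies outside the foreground, removes regions
smaller than 30 px², and relabels consecutively. In the original
two-stage design this role is played by a pretrained fluorescence
nuclei model plus manual corrections; neither is available offline, so
the watershed bootstrap is the stage-1 segmenter here and manual
correction is out of scope. The pipeline contract is unchanged — any
`(image, foreground) -> mask` function plugs in.

## Evaluation protocol

Object-level matching: candidate prediction/ground-truth pairs with
IoU ≥ 0.5 enter an exact maximum-total-IoU one-to-one assignment;
matched pairs are TP, unmatched predictions FP (a nucleus split into k
predictions scores 1 TP + (k−1) FP), unmatched ground truth FN. The
point-annotation variant matches each expert point to the instance
containing it, resolving multiple points per instance by nearest
centroid. The expert-criteria filter keeps nuclei with at least two
red signals that neither overlap a neighbour nor touch the border.

Metrics are percentages rounded half-up to one decimal; report
aggregation takes the mean (2 decimals) and the sample standard
deviation (1 decimal) of the rounded per-image values — the
conventions under which the bundled benchmark count tables reproduce
their published recall/precision/F1 rows and mean rows exactly.

## Desk-scale study conditions

The canonical experiment (`demo_scenes()`, `demo_fit()`) uses 20
scenes of 112×112 px with 8 nuclei of radius 6–9 px, noise sd 2, and
40% of nuclei overlapping a neighbour; 16 scenes train (with the
internal 80:20 split), 4 are held out. The network is depth 2 with 8
base filters and 16 rays, trained 150 epochs at learning rate 0.05
with augmentation, followed by threshold optimization on the training
patches (the 3-patch validation split alone gives too noisy an
estimate). Inference removes detected instances below 30 px², the same
small-region threshold used for pseudo-label cleanup; true nuclei at
these conditions are all above ~90 px². On one CPU the fit takes a
few minutes.

The overlap fraction matters for the baseline comparison: on fully
separated synthetic nuclei both the trained model and the
marker-controlled watershed saturate near F1 = 1, so only the
overlap-containing regime — the one the star-convex detector exists
for — discriminates between them. Overlap bites are kept shallow
(center distance 0.7–0.9 of the summed radii): with deeper bites the
z-order overlap resolution would leave the occluded nucleus as a
crescent, which is not star-convex and so falls outside the data model
the ground truth is supposed to satisfy.

The pipeline demo (`pipeline_config()`) uses smaller settings chosen
only to exercise all eight stages quickly.

## Known limitations

- The generator's simplicity means detection scores on synthetic
  scenes are far above what any method achieves on clinical WSIs; only
  orderings and mechanism-level checks transfer.
- Macenko estimation assumes exactly two stains and enough pixels of
  each above the transparency threshold; heavily silver-dominated
  regions violate this.
- The matching step's exact assignment enumerates within connected
  components of the candidate graph; at IoU ≥ 0.5 components are tiny,
  but very low thresholds on pathological inputs could make it slow.
- Training determinism holds for a fixed BLAS/thread configuration;
  bitwise reproducibility across different linear-algebra backends is
  not guaranteed.
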