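---
title: "Methods: foamy-podocyte detection and the ZEBRA score"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: foamy-podocyte detection and the ZEBRA score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the pipeline

Fabry nephropathy (FN) is the kidney manifestation of Fabry disease, a
lysosomal storage disorder in which globotriaosylceramide accumulates in
podocytes. On routine H&E/PAS histology the hallmark is subtle: podocytes
with pale, vacuolated ("foamy") cytoplasm, easy to overlook outside
specialist centers. This package implements a screening pipeline for that
hallmark:

1. **Tiling** — glomerular region annotations (QuPath-dialect GeoJSON) are
   normalized to a physical scale of 0.5 um/px and cut into 512 x 512 pixel
   tiles; scanner sources span 0.2208-0.2506 um/px, so rescaling is always
   part of the path.
2. **Classification** — a small CNN labels each tile foamy / not-foamy;
   tiles aggregate to glomeruli and glomeruli to cases by an *any-positive*
   rule, the configuration that maximizes sensitivity for a screening tool.
3. **Segmentation** — U-Net-style models delineate foamy podocytes and the
   glomerular tuft at pixel level.
4. **Scoring** — the ZEBRA score of a glomerulus is the foamy-podocyte area
   (fpA) as a percentage of total glomerular area (tgA),
   `ZS = 100 * fpA / tgA`; a case's score is the unweighted mean over its
   glomeruli, compared against a cutoff (default 0.19).
5. **Evaluation** — accuracy/precision/recall/F1/AUC/sensitivity/
   specificity/PPV/NPV with 1,000-resample percentile bootstrap CIs,
   ROC with Youden-J cutoff selection, Spearman correlation against the
   manual vacuolization score (MPVS, ISGFN 0-3 scale), Mann-Whitney and
   chi-square group tests.

Every stage is exercisable end to end on synthetic images with known ground
truth (`cmd_run_all()`), because no public FN whole-slide dataset exists.

## The synthetic world

`cohort_spec()` describes the generator's stated world. Defaults:

| parameter | default | why |
|---|---|---|
| `n_cases_pos`, `n_cases_neg` | 10, 10 | a desk-scale two-arm cohort, near the reference test split's size |
| `glomeruli_per_case` | 4-8 | scaled down from the 8-22 glomeruli of real biopsies to keep a run on one CPU under 15 minutes |
| `target_fraction_range` | 0.10-0.35 | lesioned glomeruli carry a moderate, clearly learnable burden; fractions above 0.5 are rejected as unrealistic |
| `fraction_positive_glomeruli` | 0.74 | the share of vacuolized glomeruli reported in real FN cohorts (796/1,075) |
| `source_mpp` | 0.2208 um/px | a real scanner resolution; 0.2506 and 0.25 are the other documented choices |
| `region_um` | 256 um | one 512 px tile at 0.5 um/px — the "position a box around each glomerulus" annotation workflow |
| `noise_level` | 0.02 | mild sensor-like pixel noise |

A glomerulus is drawn as a wobbly ellipse (low-order radial Fourier
perturbation) in an eosin/PAS palette; lesions are clusters of 2-10
overlapping pale discs with a darker rim, giving segmenters a learnable
texture cue without claiming biological realism. Discs are placed greedily
with rejection until the mask fraction is within ±0.01 of the target (the
recorded `true_fraction` is always the exact achieved pixel ratio, so
ground truth is never approximate). The synthetic manual score is
`MPVS = 3 * mean(true_fraction) / max_fraction + N(0, 0.15)` clipped to
[0, 3], and exactly 0 for controls — a known monotone transform that gives
Spearman checks a target.

What the generator does **not** emulate: nuclei, tubules, interstitium,
stain variation between labs, scanner artifacts, sclerotic glomeruli, or
the true per-glomerulus distribution of lesion burden (unknown; the range
is a free parameter, not a biological claim). A green test therefore
establishes that the *machinery* — scale normalization, leakage-free
cross-validation, training, scoring, statistics — is correct, not that the
models would reach any particular performance on real tissue.

## Models and training

No deep-learning framework exists in the supported R stack, so the package
carries its own small conv-net engine (Rcpp/Armadillo): 3 x 3 same-padding
convolutions via im2col, 2 x 2 max-pooling, nearest-neighbour upsampling,
ReLU, sigmoid heads, and analytic backpropagation that the test suite
checks against finite differences to ~1e-11.

* `small_cnn` (classifier): three conv blocks (8/16/32 channels), two
  poolings, global average pooling, one logit. Tiles are area-averaged to
  64 px and centered to [-1, 1] (histology is bright; zero-centered inputs
  stabilize small-net training). Loss: class-weighted binary cross-entropy
  (inverse frequency).
* `small_unet` (segmenters): two-level encoder-decoder with skip
  connections (8/16/32 channels, ~25k parameters) at a 128 px working
  resolution; per-pixel weighted BCE with the positive-class weight capped
  at 20.

Optimization is minibatch Adam (classifier lr 0.002, batch 4; segmenter lr
0.003, batch 8; both 5 epochs) with a step decay to lr/3 over the final
third of the epochs. Because a from-scratch net this small occasionally
fails to leave the constant-output basin within 5 epochs, the classifier
uses deterministic random restarts (up to 6, in the spirit of
`kmeans(nstart = )`): a failed fit is detectable on the *training* data
alone (training accuracy below 0.95), so no validation information leaks
into the choice. All randomness — weight init, shuffling, augmentation,
restarts — derives from one seed; identical seeds give bit-identical fits.

The named large backbones (ResNet18, EfficientNetB2, DenseNet121, Swin-T;
DeepLabV3+, SegFormerB4) and foundation-model embeddings are recognized in
the config enums but raise an informative error: they are plug-in points,
not part of this build.

Augmentation (off by default, `augment = TRUE` to enable) is the
label-preserving set: horizontal/vertical flips, rotations by multiples of
90 degrees, brightness/contrast jitter ±10%, hue jitter ±5% of the hue
circle; geometric parts apply identically to masks.

## Cross-validation and aggregation

`make_case_folds()` shuffles case ids under a seed and deals them
round-robin into k = 5 folds, so fold sizes differ by at most one case and
*every tile of a case shares its fold* — the property that prevents
patient-level leakage, checked exhaustively in the tests. Tile predictions
pool to a glomerulus by `any_positive` (default; `majority` and
`mean_prob` selectable), and glomeruli to a case by "positive iff any
glomerulus positive". The aggregation unit is configurable (`case` or
`slide`) because real cohorts report the screening unit ambiguously.

## Numerical choices

* **Coordinates** are 0-based, y-down; pixel (r, c) covers
  [c-1, c] x [r-1, r] with center (c-0.5, r-0.5). Tile windows are
  half-open, `[x, x+512) x [y, y+512)`.
* **Tile inclusion**: a tile is kept when its *center* lies inside the
  region polygon; a region whose bounding box fits in one tile yields
  exactly one padded tile centered on the box.
* **Tile labeling**: any positive-area intersection with a lesion polygon
  (exact Sutherland-Hodgman clipping, no minimum-overlap threshold) makes
  a tile foamy.
* **Interpolation**: bilinear for images, nearest-neighbour for masks
  (masks must stay binary); integer-factor shrinking uses exact block
  averaging, which composes exactly across stages.
* **Dice/IoU conventions**: two empty masks score 1 (a correct rejection is
  perfect agreement); the default pooled metric is `global_pixel`, which
  sidesteps the convention entirely, and `per_tile_mean` is always reported
  alongside.
* **Undefined ratios** (zero denominators) are `NA`, never 0, and
  bootstrap resamples with undefined metrics are skipped and counted
  (> 50% undefined is an error).
* **Youden cutoff**: J is evaluated at every midpoint between adjacent
  sorted unique scores; ties break toward the lower cutoff, favouring
  sensitivity. Case classification against the cutoff is inclusive
  (`mean ZS >= cutoff` is positive) for the same reason.
* **Mann-Whitney**: U from mid-ranks; the two-sided p comes from exhaustive
  enumeration of assignments when n <= 12 (valid under ties) and from the
  tie-corrected normal approximation otherwise.
* **Chi-square**: Pearson, df = 1, no continuity correction by default
  (flag available).
* **Bootstrap**: 1,000 resamples of individual (prediction, label) pairs —
  the resampling unit follows the stated protocol; a case-level cluster
  bootstrap would be a conservative alternative but is not the default.

## The ZS scale ambiguity

Printed reference values for the score (case means 0.49 vs 0.10, cutoff
0.19, glomerular 0.5 ± 2.4) are not reconcilable with a single
percent-or-fraction convention. This package computes ZS in **percent**
(`100 * fpA / tgA`, matching "fpA/tgA %") and documents the ambiguity
rather than guessing; the default cutoff 0.19 is stored as given. On
synthetic cohorts the package derives its own cutoff via `youden_cutoff()`
instead of relying on the literature value.

## Design decisions that were genuinely open

* **Package shape**: this is a multi-stage pipeline tool, not a single
  estimator, so the package exposes per-module function surfaces plus two
  pipeline commands (`cmd_simulate()`, `cmd_run_all()`) and a thin Rscript
  front-end (`inst/scripts/zebra.R`), rather than one fitting function with
  S3 model methods.
* **Grid vs single tile per glomerulus**: tiles are extracted on a grid
  over the region's bounding box; the one-tile-per-glomerulus workflow is
  obtained by using 256 um templates (`make_region_templates()`), which is
  exactly what the default synthetic world does.
* **Working resolutions** (64 px classifier, 128 px segmenter) trade
  boundary precision against CPU time; at the default glomerulus size the
  induced Dice loss is small relative to the acceptance margins.
* **Restart strategy** (above): chosen over longer training to respect the
  5-epoch budget of the stated evaluation protocol.

## Known limitations

* The synthetic lesion texture is far easier than real vacuolated
  podocytes; segmentation Dice on real tissue would be much lower (the
  reference workflow reports <= 0.63 for the best model).
* The small nets are not meant to transfer to real WSIs; the WSInfer-style
  bundle exists for interface compatibility, not weight reuse.
* Pyramidal WSI decoding is out of scope; inputs are region crops or flat
  images.
* No multiple-testing correction is applied anywhere (the evaluation
  protocol applies none).
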