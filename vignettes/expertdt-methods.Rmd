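---
title: "Methods: pathologist-guided hierarchical tile classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pathologist-guided hierarchical tile classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ExpertDT)
```

## The problem and the model

Subtyping renal cell neoplasms -- clear cell (ccRCC), papillary (papRCC)
and chromophobe (chrRCC) carcinomas and the benign oncocytoma (ONCO) --
from H&E histology is difficult because morphologies overlap, most
notoriously between chrRCC and ONCO and between ccRCC and papRCC. ExpertDT
encodes the pathologist's diagnostic workflow as a tree of three binary
decisions applied to every image tile:

1. **Root** -- tumor (T) vs not-tumor (NT), where NT pools fiber, necrosis
   and normal renal parenchyma;
2. **Node** -- the super-label (ccRCC, papRCC) vs (chrRCC, ONCO), the split
   a pathologist finds easiest;
3. **Leaves** -- the two hard differential diagnoses, chrRCC vs ONCO
   (leaf1) and ccRCC vs papRCC (leaf2), each seen only by tiles routed into
   its super-group.

Each stage is an independent binary classifier trained on the reduced tile
subset showing only its two label groups, balanced by random
under-sampling. The package is classifier-agnostic: any object honoring the
`fit` / `predict` / `predict_score` contract can back a stage. The shipped
default is a ridge-penalized logistic regression over hand-specified
texture descriptors (intensity moments and quantiles, an 8-bin histogram,
two-lag gradient magnitudes per axis, Laplacian energy), chosen because it
is CPU-fast and exactly seed-reproducible; the tree logic, not the
backbone, is the method under study. The two naive topologies
(`tree_spec("naive1")`, `tree_spec("naive2")`) are the only other node
partitions of the four subtypes and serve as controls for the value of the
expert layout.

At test time an image is cut into a regular grid of complete
`tile_size_px` squares (border remainders dropped, so every classifier
input has homogeneous statistics), each downscaled with exact area
(interval-overlap) interpolation to `model_input_px`. A tile whose
channel-averaged mean intensity at source resolution is **strictly
greater** than 210 is background: never classified, never voting. The
threshold is applied at source resolution; the boundary value 210 itself
counts as tissue.

## Refine

Downstream of each stage, every classified tile is relabelled by the
majority label of its 9-connected neighborhood (the eight touching tiles
plus itself), with background and out-of-stage cells excluded from the
vote. Three conventions are fixed here because a single-pass filter leaves
them open:

* **synchronous update** -- all votes are read from the input map, so the
  result is independent of scan order, as befits a low-pass filter;
* **single pass** per stage, not iteration to convergence;
* **ties keep the original label**; tied maxima occur routinely at map
  borders and near masked regions, and keeping the original is the only
  choice that makes a uniform map a strict fixed point of every tie variant.

Labels, not confidences, are voted.

## Patient aggregation and node pruning

The patient's diagnosis is the plurality subtype over all final tile
labels pooled across the patient's images, NT tiles excluded. A patient
with no tumor-predicted tile yields the distinct outcome `NO_TUMOR`. Exact
ties are broken by subtype prevalence order (ccRCC > papRCC > chrRCC >
ONCO), with a warning.

The node performs the most error-prone split when a specimen shows large
areas compatible with both super-groups. The pruning rule therefore
computes, per patient, the relative super-label imbalance
$|n_1 - n_0| / (n_1 + n_0)$ pooled over all the patient's images. Under the
`selective` policy the node is trusted only when this imbalance is **not
below** 0.30; otherwise the node is pruned and every tumor tile is scored
by *both* leaves, taking the label of the leaf whose confidence
($2\,|s - 0.5|$, with $s$ the contract score) is larger, ties going to
leaf1 with a warning. This keeps one vote per tile so the aggregation step
is unchanged. The relative (scale-free) normalization was chosen because
patients contribute very different tile counts; an absolute 30-point gap
would make the rule depend on specimen size.

Boundary conventions: the rule fires on strict inequality, so imbalance
exactly 0.30 trusts the node; `imbalance_threshold = 0` therefore never
fires and reproduces the `unpruned` ablation exactly, while
`imbalance_threshold = 1` is defined as "never trust the node" and
reproduces `node_pruned` exactly (a unanimous patient has imbalance exactly
1, so strict inequality alone could not express "always prune").

## Tunable parameters

| parameter | default | unit | role |
|---|---|---|---|
| `tile_size_px` | 1000 | px | source tile side; the scale a pathologist reads |
| `model_input_px` | 112 | px | classifier input after area downscaling |
| `background_mean_threshold` | 210 | intensity | strictly-greater background rule |
| `imbalance_threshold` | 0.30 | fraction | selective node pruning |
| `max_epochs` / `patience` / `batch_size` | 150 / 20 / 128 | -- | advisory, for iterative backbones |
| `fraction` (patient split) | 0.75 | -- | train/validation patient split |

## The synthetic cohort generator

`generate_cohort()` provides end-to-end material with the statistical
structure the method assumes, not visual H&E realism. Each tissue class is
a band-limited Gaussian random field: mean intensity encodes the
between-pair axis (at `delta_between = 1`, the (cc, pap) pair sits at 125
and the (chr, ONCO) pair at 175), texture contrast encodes the within-pair
axis (at `delta_within = 0.3`, sibling contrasts are 20.5 vs 29.5 around
25), and the three NT tissues sit apart from all tumor classes. Per-tile
log-normal contrast jitter (sd 0.25) and mean jitter (sd 6), plus per-pixel
noise (sd 15), make single-tile within-pair calls genuinely fallible --
that is the regime in which Refine and patient voting earn their keep --
while the between-pair split stays easy, mirroring the intended hierarchy
of difficulty. At `delta_within = 0` the siblings are drawn from the same
distribution by construction.

Images are composed on the tile lattice: a one-cell near-white (> 240)
background margin, a rectangular tumor region of the patient's subtype
covering about 70% of the interior (the approximate tumor/not-tumor tissue
ratio of a surgical cohort), and one NT tissue filling the rest. Slides
per patient follow a truncated geometric distribution with mean 2.2
(capped at 6). Mixed-morphology patients (`make_ambiguous_patient()`) fill
the tumor region with **contiguous blocks** of the two super-group
textures in the requested proportion; mixing i.i.d. per cell was rejected
because Refine coarsens salt-and-pepper patterns and the pruning statistic
then no longer reflects the intended area proportions -- and the clinical
motivation is precisely large coexisting areas of different morphology.

What passing tests on this generator does **not** show: robustness to
stain variation, nuclei-scale morphology, scanner artifacts, polygonal
tumor boundaries, or class frequencies of a consecutive clinical series.
The generator's cell-aligned regions also make tile extraction noiseless
at region borders, which flatters all arms equally.

## Numerical and design choices

* Coordinates are 0-based, half-open pixel intervals; grids are row-major.
* ROI training grids are anchored at each ROI's top-left corner,
  independent of the test-time image grid.
* Downscaling uses exact interval-overlap (area) weights -- a ~20-line
  weight-matrix product -- rather than bilinear sampling, to avoid
  aliasing at the ~9x reduction the default geometry implies.
* Stage encodings are fixed (T = 1 at root; (ccRCC, papRCC) = 1 at the
  expert node; the second-named subtype of each leaf pair = 1) so scores
  are comparable across runs.
* For the naive trees, leaf1 always covers the node's group 0; the group
  ordering follows the published leaf listings (pap vs ONCO / chr vs cc
  for naive1; pap vs chr / ONCO vs cc for naive2).
* Degenerate fits (all features constant) fall back to a majority-class
  scorer with a warning rather than failing.
* The multiclass MCC uses the covariance-form generalization; degenerate
  tables (one true and one predicted class) are defined as 0 with a
  warning.
* The per-class recall spread is the population standard deviation (divide
  by the number of classes): it summarizes exactly four numbers, not a
  sample.
* All randomness (under-sampling, splits, texture synthesis) flows from
  explicit seeds through a private RNG scope, so no call disturbs the
  caller's RNG state.

## Problem sizes

The package's own evaluations use a 40-patient cohort (10 per subtype,
60/40 patient-level split, ~2.2 slides per patient, 7x7 cells of 64 px
tiles downscaled to 32 px). These sizes give every arm a few thousand
training tiles and keep a full generate/train/ablate cycle in the tens of
seconds on one CPU while leaving enough tiles per patient (~35 tumor
tiles) for voting to be meaningful. Property tests on the Refine operator
use up to 20x20 maps with 2-5 labels against a brute-force recount oracle;
metric implementations are cross-checked against independently coded
closed forms on 1000 random confusion matrices.

## Known limitations

* Only rectangular ROIs; polygonal annotations would need a mask-based
  extractor behind the same interface.
* Plain rasters only (PNG/TIFF); pyramidal whole-slide formats would plug
  in at `read_raster()`.
* The default backbone is intentionally simple; with strongly non-linear
  class structure it underperforms a CNN, and the tree inherits that.
* The pruned route's both-leaves scoring asks each leaf about tiles
  outside its training distribution; confidences there are extrapolations,
  which is why `node_pruned` degrades sharply -- consistent with the
  reported importance of the node stage.
```{r session}
sessionInfo()
```
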