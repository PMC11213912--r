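---
title: "Methods: region-constrained panoptic segmentation and TIL scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: region-constrained panoptic segmentation and TIL scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(tilquant)
```

This vignette is the package's own account of its models and the design
choices behind them. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The problem and the modeling idea

Stromal TILs — lymphocytes and plasma cells infiltrating the stroma
between carcinoma nests — carry prognostic information in breast cancer,
but visual scoring is subjective. The pipeline here is a *concept
bottleneck*: a segmentation model first produces interpretable concepts
(tissue regions at low magnification, classified nuclei at high
magnification), and the TIL score is then plain arithmetic on those
concepts. Errors are attributable: a wrong score can be traced to a wrong
region or a misclassified nucleus.

## Class vocabularies and the compatibility kernel

Six region classes (cancer, normal epithelium, stroma, TILs-dense,
necrosis/debris, empty) and six nucleus classes (cancer, normal
epithelium, fibroblast, lymphocyte, plasma cell, debris), integer codes
1..6 with 0 reserved for unannotated/background so masks double as loss
weights. Both vocabularies group onto the practical superclasses
{epithelium, stroma, TILs, other}; evaluation at the grouped level is
more reliable because fine distinctions (e.g. normal vs cancer epithelium
at 10x) have low annotator agreement.

The compatibility kernel `K[region, nucleus]` encodes hard biological
exclusions. Only one entry is universally uncontroversial (no fibroblasts
inside epithelial nests), so the shipped default is a documented,
config-overridable choice:

* epithelial regions prohibit fibroblasts and free debris;
* stromal regions (stroma, TILs-dense) prohibit epithelial nuclei;
* necrosis admits debris plus the mononuclear cells commonly found at its
  margins;
* the *empty* region admits everything — an empty region carries no
  evidence about nucleus class, and prohibiting all classes would leave
  the attention map without admissible mass.

## The two-branch network

Two parallel U-Nets (default depth 5, base width 32; all tests use a
depth-3, width-8 toy profile). The region branch sees a
`roi_input_px` square at 1 MPP; the nucleus branch sees the central half
of that footprint at 0.5 MPP (hence the same pixel extent). Two couplings
run from the region branch to the nucleus branch:

1. **Feature hook.** The region decoder's feature map at `hook_level`
   (counted up from the bottleneck, default 2) is center-cropped to the
   HPF footprint, nearest-neighbor upsampled, and concatenated onto the
   nucleus decoder at the same level. A single mid-decoder concatenation
   is the minimal reading of cross-resolution context sharing; nearest
   neighbor is used because it preserves feature values exactly.
2. **Constraint.** Region probabilities (softmax of the ROI head,
   center-cropped and nearest-upsampled to the HPF grid — nearest again
   because it preserves distributions) are mixed with the kernel and a
   learned prior into class-specific attention maps
   `A_c(x) = Σ_r ρ_r(x) K[r,c] P[r,c]`, renormalized over classes.
   Exact zeros are preserved: under a one-hot region, a prohibited class
   has attention exactly zero, and therefore constrained probability
   exactly zero. (An earlier floor-then-renormalize variant leaked
   prohibited probability above tolerance when logit contrast was large;
   the degenerate-pixel fallback — uniform over the argmax region's
   admissible classes — handles the only case the floor was protecting.)
   At inference the soft mixture is used rather than the argmax region,
   so uncertainty at region boundaries propagates into the nucleus
   classifier.

The constrained distribution re-weights only the foreground-conditional
part: background keeps its probability, the six class probabilities are
multiplied by `A_c` and renormalized to the remaining foreground mass.
This makes the constraint *conservative*: with an all-ones kernel and
uniform priors it is exactly the identity, a property the test suite
checks to 1e-6.

**The prior `P`** is a free logit matrix passed through a row-softmax
restricted to kernel-admissible entries, initialized uniform. It receives
gradient only from the constrained loss term. The region probabilities
entering the attention map are treated as constants in the backward pass:
the constrained term shapes the nucleus branch and the priors, while the
region branch is supervised by its own two loss terms. This avoids the
degenerate solution where the region branch distorts regions to make
nucleus classification easier.

## Loss

Four equal-weight components, each `cross-entropy + (1 − soft-Dice)`
(Dice averaged over classes, smoothing constant 1): ROI regions at 1 MPP,
HPF-footprint regions at 0.5 MPP (the cropped ROI head — no separate
decoder head, the simpler reading of the two-scale region supervision),
unconstrained nuclei, constrained nuclei. The per-task loss form is a
design choice; cross-entropy gives well-scaled gradients early, Dice
counteracts class imbalance. Smoothing 1 (rather than a tiny epsilon)
bounds the Dice gradient for classes with vanishing predicted mass —
with epsilon smoothing the gradient scales like `1/Σp`, which destabilized
training.

Region components ignore code-0 (unannotated) pixels. For the nucleus
components, code 0 is the *background class* and is supervised as its own
channel — ignoring it would make background unlearnable and instance
extraction impossible; the nucleus components instead inherit their
ignore mask from unannotated region pixels.

Training (`train_toy()`) is plain Adam with global gradient-norm clipping
at 5 (the Dice term produces occasional large gradients early), one
sample per step cycling deterministically, and all randomness behind one
seed. This is a desk-scale loop for overfitting small synthetic sets, not
a production trainer; the test suite overfits 5 synthetic ROIs (96 px at
0.5 MPP) in 300 steps (~1 minute on one CPU) to grouped region Dice
above 0.9.

## Instance extraction

Foreground = argmax ≠ background on constrained probabilities;
4-connected components; components under `min_instance_px = 10` px at
0.5 MPP dropped (about the smallest plausible lymphocyte cross-section);
instance class probabilities are the mean constrained probabilities over
the component renormalized over the six classes, argmax class with ties
broken toward the lower class code for reproducibility.

## Stain deconvolution and informativeness

Optical density `od = -log10((rgb + 1)/256)`. The masked Macenko
estimator uses pixels with mean RGB < 220 and OD magnitude > 0.05 (the
"masked" part — plain Macenko is skewed by white glass), projects them
onto the top-2 singular plane and takes the 1st/99th percentile angular
extremes as stain directions; hematoxylin is the column with the larger
red/blue OD ratio (hematoxylin transmits blue). Per-tile estimation falls
back to the standard reference vectors on degenerate tiles. Tile
informativeness = mean(H)·mean(E) over tissue pixels (zero when tissue
fraction < 5%): jointly hematoxylin- and eosin-rich tiles — peritumoral
stroma — rank first. Only the ranking matters downstream; the absolute
scale depends on OD units.

## Whole-slide pipeline

Thumbnail at 8 MPP; tissue = saturation > 0.05 and value < 0.95, closed
with a small disc; ink exclusion removes saturated connected components
whose 12-bin hue histogram has peak purity > 0.8. Tiling uses a
non-overlapping grid (default footprint 512 µm so one tile equals one
analysis ROI; synthetic test slides use 48 µm tiles for the same
geometry at desk scale), scores every tile at 2 MPP, sorts by
(informativeness desc, row, col), and analyzes the top `top_k = 300`
tiles — a fixed budget that makes runtime near-constant per slide. The
300-ROI cap is applied after artifact exclusion. Selected ROIs are dealt
cyclically over the 5 cross-validation models (`rank mod 5`); optionally
every ROI is run through all 5 members and the probability maps averaged.

## Scores, saliency, calibration

Per ROI: stromal compartment = stroma + TILs-dense regions (excluding
TILs-dense would delete precisely the signal being scored); membership by
instance centroid; debris excluded from all cell counts; areas in mm²
from pixel counts. Variants: `nTSa` (TILs per stromal mm², a density),
`nTnS`, `nTnA` (fractions). Zero denominators give missing values, never
zero. Slide level: global pooling of counts, or saliency-weighted
averaging with weight = fraction of tile pixels that are stroma within
32 µm of the tumor boundary (Euclidean distance transform; the denominator
is all tile pixels, taken literally). Calibration: z-score both score
lists, flag slides with standardized disagreement > 1.96, fit
`k = Σ vis·comp / Σ comp²` on inliers, return `k·comp` for *all* slides —
outliers are excluded from fitting only. Survival-analysis thresholds
(10% stromal score, 3% nTnA) are exposed as constants but survival
modeling is out of scope.

## Evaluation conventions

Hospital-stratified folds: hospitals shuffled (seeded), ordered by size,
greedily dealt to the smallest fold, so no hospital spans training and
testing. Fold summaries: fold 1 is reserved for tuning; reported values
are mean ± *sample* (n−1) sd over folds 2–5, rounded half-away-from-zero
to one decimal. This convention is discriminating: the shipped reference
fold table reproduces its printed summaries only under sample sd
(population sd fails, e.g. for the stromal Dice row). Instance matching
is greedy centroid-in-annotation with nearest-centroid tie-break; on
non-overlapping ground truth it coincides with optimal assignment.
AUROC is the midrank statistic, verified exhaustively against
concordant-pair counting on fixtures up to 50 items.

## The synthetic generator

The generator emulates: ROI geometry (square fields at 0.5 MPP with a
paired 2x box-filtered 1 MPP view; default 1024 px), region layouts
(half-plane, elliptical tumor blobs with a TILs-dense rim and a glass
strip, necrotic-core rings, pure stroma, background), non-overlapping
nucleus instances placed by dart-throwing (max 50 rejections; an
exclusion ring one pixel wide keeps instances 4-disconnected so instance
extraction is exact), class mixes sampled per region consistently with
the default kernel, and Beer–Lambert rendering
`rgb = 255·exp(−S·c)` with hematoxylin concentrated in nuclei and eosin
in stroma/cytoplasm. Defaults: stromal cellularity 3000 nuclei/mm²
(TILs-dense double, epithelium 6000) and mean nucleus radius 6 px at
0.5 MPP — values a pathologist would call plausible for cellular breast
stroma; TIL fraction applies as an i.i.d. Bernoulli across the stromal
compartment so slide-level `nTnS` is binomial around it by construction.

What it does *not* emulate: chromatin texture, staining batch effects,
overlapping/touching nuclei, out-of-focus regions, real tumor
architecture. Passing tests therefore demonstrate correctness of the
*mechanisms* (constraint algebra, counting, geometry, calibration,
training dynamics on separable data) — not accuracy on real slides,
which requires real annotations and full-scale training.

Natural-log rendering against base-10 optical density means recovered
concentrations differ from generating ones by the constant `ln 10`; the
round-trip test therefore checks correlation (> 0.99), while exactness
(1e-3) is checked on tiles constructed directly in OD space.

## Numerical choices and degenerate inputs

* Attention: exact zeros preserved; degenerate pixels (no admissible
  mass) fall back to uniform over the argmax region's admissible classes,
  then all classes with a warning.
* Constrained renormalization needs no epsilon: softmax is strictly
  positive and every kernel row admits a class, so the foreground
  normalizer is positive.
* All-ignore loss targets contribute 0 with a warning.
* Dice smoothing 1; cross-entropy epsilon 1e-8.
* Ties: argmax ties break toward the lower class code; tile-rank ties
  break row-major; matching ties break by nearest centroid.
* Problem sizes in the tests (96–256 px ROIs, 400-tile slides, 300-step
  toy training) were chosen as the smallest sizes at which the binomial
  and overfit checks have comfortable margins.

## Known limitations

Single-threaded CPU training only; no augmentation; the WSI backend reads
synthetic tile directories (pyramidal formats would need an external
reader); constraint gradients are detached from the region branch by
design; the shipped kernel beyond the fibroblast-in-tumor rule is a
documented default, not ground truth.
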