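---
title: "Active learning for multi-class histology segmentation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Active learning for multi-class histology segmentation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Pixel-level annotation of H&E-stained tissue is the bottleneck of semantic
segmentation in computational pathology: labeling one region of interest
(ROI) takes an expert pathologist substantial time, and a multi-class
segmentation model needs many ROIs to generalize. Active learning (AL)
attacks the bottleneck by spending the annotation budget where the current
model is worst: a bootstrap classifier trained on a few ROIs predicts tissue
maps for the unlabeled pool, a quality-assurance (QA) step grades those maps,
and the worst-graded ROIs are annotated and added to the training set before
retraining. The claim of interest is *directional*: at a matched training-set
size, AL should match or beat random selection (RL) of the same number of
ROIs.

`alseg` implements this pipeline end to end for an oral cavity carcinoma
style class system — 11 tissue classes (stroma, tumor, lymphocytes, mucosa,
background/adipose, blood, nerves, necrosis, keratin pearl, muscle, junk)
plus an "avoid" class for unlabeled pixels — together with a synthetic cohort
generator that stands in for the private clinical dataset, and a simulated
QA oracle that stands in for the pathologist panel. Everything downstream of
those two stand-ins (preprocessing, model, training, metrics, selection loop,
comparison statistics) is the real pipeline.

## Data model and label encoding

Label maps are RGB PNGs in which each tissue class owns one exact color; a
`class_legend` maps colors to contiguous integer indices `0..K-1`, with the
largest index reserved for avoid. The annotation protocol names colors
("Red", "Sky blue", ...) without RGB values, so the package fixes one
canonical palette and writes it into every cohort manifest; avoid uses pure
white, which no tissue class uses. Decoding is exact-match only, with a
strict mode that reports unknown colors instead of silently mapping them to
avoid — label PNGs are lossless, so an unknown color means a corrupt input,
not compression noise.

Slide background and adipose tissue present identically (bright, nearly
white), so the 12-class annotation legend is fused into 11 working classes by
`merge_classes()`, which relabels pixels, drops one legend entry and
re-compacts indices.

Cohorts are split **by patient** (`split_by_patient()`): all ROIs of a
patient land on one side, because ROIs of the same patient share appearance
(stain batch, tissue characteristics) and splitting within a patient would
leak that appearance into the holdout.

## Preprocessing

ROIs are resampled to a common physical resolution (2 µm/px by default)
with bilinear interpolation for images and nearest-neighbour for label maps
— nearest-neighbour indexing cannot invent a class index that was not in the
source. Fixed spatial dimensions come from a centered crop; when an input is
smaller, an explicit `pad` policy fills labels with avoid and images with the
dataset-mean color (default is to reject).

"Standardization to the dataset mean" is read as subtract-mean-divide-by-sd
per channel, with a mean-only mode (`mode = "center"`) preserving the literal
mean-subtraction reading; whether the reference pipeline divided by the
standard deviation is not documented, and full standardization is the safer
default for optimization. Statistics are computed **once over the training
pool** and frozen for validation and holdout images, so no holdout
information leaks into preprocessing; a 1e-6 floor on the standard deviation
guards degenerate constant channels.

## The segmentation network

The classifier is a compact U-net-style fully convolutional network:

* encoder: 4 blocks of [space-preserving 3×3 convolution → batch norm →
  ReLU → 2×2 max pool], with dropout after each pool during training;
* decoder: 4 mirrored blocks of [nearest-neighbour 2× upsample →
  concatenation with the matching encoder block's pre-pool output → 3×3
  convolution → batch norm → ReLU];
* head: 1×1 projection to 11 softmax outputs.

Design points that the reference description leaves open, and the choices
made here:

* **Upsampling** is nearest-neighbour followed by a convolution, not a
  transposed convolution — matching the stated ordering "up-sampling layer
  followed by a space-preserving convolutional layer".
* **One convolution per block** (the block descriptions use the singular),
  unlike the original two-convolution U-net; the count is configurable.
* **Channel widths** are unspecified; the default doubles from
  `base_channels` per level. Desk-scale runs use `base_channels = 4`
  (see below), the constructor default is 16.
* **Optimizer**: Adam, the de-facto standard where none is named; the name
  is recorded in the training config for audit.
* **Dropout rate 0.8** is taken at face value as the drop probability,
  applied after each max pool at training time only. It is unusually
  aggressive, so it is configurable; the desk preset uses 0.25.
* **Batch normalization at batch size 1** normalizes each channel over its
  spatial extent; inference uses running statistics (momentum 0.1), so
  repeated inference is bit-identical.

The loss is masked categorical cross-entropy: the mean of `-log p(true
class)` over labeled pixels only. Avoid pixels contribute neither loss nor
gradient — annotators label only regions they are confident about, so the
unlabeled remainder must not push the model anywhere. A pixel whose true
class receives probability below 1e-12 is clamped (with a warning) rather
than producing an infinite loss.

The whole network is implemented in the package (im2col-based convolution,
pooling, upsampling and fused batch-norm/ReLU kernels in C++ via
RcppArmadillo; orchestration, Adam and the loss in R). Backpropagation is
verified against central finite differences in the test suite at tolerance
1e-4, and a capacity check overfits one easy synthetic ROI to Dice ≥ 0.95
within 200 epochs.

## Metrics

All holdout metrics pool pixel counts across the entire holdout set
("micro-pooling") before computing anything, rather than averaging per-image
metrics — per-class counts are accumulated over all images, and

\[ \mathrm{dice}_c = \frac{2\,TP_c}{2\,TP_c + FP_c + FN_c} \]

is evaluated on the pooled counts. Classes absent from the holdout ground
truth are reported as undefined (`NA`), never as 0, and the summary "mean
Dice" is the **unweighted mean over defined classes** — prevalence-weighted
averages would be dominated entirely by stroma and tumor.

One-vs-all ROC AUC per class uses the class probability as score, that
class's labeled pixels as positives and all other labeled pixels as
negatives, computed by the tie-corrected rank (Mann–Whitney) statistic; this
equals trapezoidal ROC integration exactly and is testable against exhaustive
pair counting. Loss curves are smoothed for display by a centered 3-epoch
moving average with edge truncation.

## The selection loop and its oracle

One experiment comprises:

1. **Bootstrap**: 4 ROIs drawn uniformly from the training pool form D0;
   classifier C0 trains on them.
2. **Iterate** (3 rounds): the current classifier predicts every
   never-selected pool ROI; each tissue map is graded 0–5 per class present
   in its ground truth; the 4 ROIs with the lowest mean grade join the
   training set; the classifier retrains **from fresh initialization** on
   the enlarged set ("the classifier was re-trained"; fresh starts also keep
   the AL/RL comparison clean of warm-start confounds).
3. **Control**: the identical procedure with uniformly random additions
   (without replacement from the never-selected pool), run in triplicate
   from the same D0; metrics are summarized as mean ± sd over batches.

The human QA panel is replaced by a simulated oracle: for each class present
in the ground truth it computes the per-image Dice `d_c` and grades
`round(5 d_c)` (half-up), optionally perturbed by integer-rounded Gaussian
noise clamped to 0–5. The image-level score is the unweighted mean of class
grades — the reference procedure grades per class but selects per image
without stating the aggregation, and the unweighted mean is the simplest
rule consistent with it. Ties are broken lexicographically by ROI id so
selection is fully deterministic. Note the quantization is part of the
oracle's definition: with a noise-free oracle, selection equals the k-argmin
of per-image mean *quantized* grades, which the tests verify against an
independent brute-force recomputation; an unquantized aggregate would be a
different (slightly more informative) grader than a 0–5 scale supports.

Each training round holds out 25% of the current training set (at least one
ROI, drawn deterministically per round) from gradient updates as a
validation set for the per-epoch validation loss; the reference experiments
plot validation loss without defining its split, and an internal fraction is
the only construction that works at every training-set size.

**Seed discipline.** One experiment seed drives everything through labeled
streams (`derive_seed(seed, "bootstrap")`, `... "rl", batch, iteration`,
`... "init", iteration`, `... "val", ...`, `... "oracle", ...`), hashed by an
integer recurrence that stays below 2^31. AL and all RL batches therefore
share D0 and the per-iteration initialization seeds exactly, which makes the
comparison paired by construction: at every iteration `|D_i|` is identical
across strategies and batches (budget parity).

**Comparison statistic.** The final AL classifier's per-class holdout Dice
is paired with the across-batch mean of the final RL classifiers' per-class
Dice, and the paired differences are tested with a two-sided Wilcoxon
signed-rank test. The reference analysis reports a significance level
without naming a test; a nonparametric paired test is the defensible choice
at ~8 paired classes and is recorded as such. With fewer than 3 paired
classes the test is skipped with a notice. A second test
(`gt_pixel_parity()`) checks that AL did not simply promote ROIs with more
annotated pixels: the per-iteration totals of added non-avoid ground-truth
pixels are compared between AL and RL with a two-sided rank-sum test.

## The synthetic cohort

The generator reproduces the *statistical structure* that makes the AL
question non-trivial, not histology itself:

* **Blob grammar, not i.i.d. noise**: stroma background, irregular tumor
  nests (unions of jittered ellipses), keratin-pearl cores and necrosis
  carved inside tumor, lymphocyte infiltrates hugging the tumor border, a
  background/adipose margin with optional mucosal lining, and rare
  muscle/nerve/blood/junk patches. AL only matters when ROIs differ in which
  structures they contain.
* **Imbalanced prevalence**: tumor ≈ 0.22, lymphocytes ≈ 0.10 of the image,
  six classes at or below 0.02, stroma absorbing the rest; rare classes are
  present in only ~40–50% of ROIs (with their conditional share scaled so
  the cohort-level expectation matches the target), so per-ROI class
  inventories genuinely vary.
* **Avoid borders**: ~10% of labeled pixels (jittered ±25% per ROI to mimic
  varying annotator thoroughness) are re-masked to avoid by eroding
  annotation boundaries — confident interiors keep labels, boundaries do
  not.
* **Appearance**: H&E-like per-class mean colors (pink stroma, purple tumor,
  dark lymphocytes with dot texture, near-white background) plus spatially
  correlated noise whose amplitude scales with a `hardness` knob
  (`4 + 26·hardness` gray levels), a per-patient color shift (making
  patient-level splitting consequential), and white pixel noise. The tests
  verify that a fixed training recipe scores lower at hardness 0.8 than at
  0.1 in a majority of seeds — the knob provably changes task difficulty.
* **Determinism**: every ROI derives its own seed from the cohort seed, so a
  config + seed pair reproduces the cohort bit for bit.

The preset cohort mirrors the reference study's shape: 23 patients, 24 ROIs
(one patient contributes two), 3 holdout patients, 21-ROI training pool —
hence D0 of 4, three additions of 4, and 5 never-selected ROIs at the end.

What the generator does *not* emulate: real stain variation and artifacts,
texture beyond color statistics (classes are separable mostly by color and
local context), annotation disagreement between pathologists, and gigapixel
WSI scale. Passing the desk-scale tests therefore demonstrates that the
pipeline's decision structure behaves as claimed under controlled conditions,
not that the specific Dice levels transfer to clinical imagery.

## Desk-scale study conditions

CPU-scale runs use fixed "desk" settings chosen once: 128×128 ROIs at
2 µm/px (side divisible by 2^4, as the architecture requires),
`base_channels = 4`, dropout 0.25, and 30 epochs per round at learning rate
1e-3 with batch size 1 — the full-scale recipe (300 epochs at 1e-4, dropout
0.8) scaled by 10× fewer epochs with a 10× larger step and lighter
regularization, keeping the optimization in a comparable regime at roughly
1% of the pixel count. The acceptance checks run this configuration for
three experiment seeds and ask for the directional result (final AL mean
Dice ≥ final RL mean over batches; final AL validation loss ≤ RL's) in a
majority of seeds. At this scale the trained models show the qualitative
pattern of the full-scale study: common classes (stroma, tumor, lymphocytes,
background) reach Dice ≈ 0.7–0.98 while rare classes sit near 0.

## Numerical choices and degenerate inputs

* Softmax is computed with per-row max subtraction; per-pixel probabilities
  sum to 1 within 1e-5 (tested).
* Cross-entropy clamps true-class probabilities at 1e-12, with a warning.
* Batch-norm uses eps 1e-5; dataset-statistics sd is floored at 1e-6.
* Argmax tissue maps break probability ties toward the lowest class index.
* An all-avoid training map is accepted with a warning (it contributes no
  gradient); an all-avoid image is an error where a grade or loss is
  requested, because those quantities are undefined.
* `select_lowest()` with fewer candidates than requested returns all of
  them with a warning; an exhausted pool stops the loop early with a
  warning and a truncated record list.
* Empty 0×0 label maps encode to empty rasters; crop and resize reject
  non-positive target dimensions.

## Known limitations

* The network trains at batch size 1 only (as in the reference recipe); no
  augmentation, transfer learning or multi-GPU support — none are part of
  the ROI experiments being reproduced.
* AUC pooling across the holdout stores per-pixel class probabilities; at
  whole-slide scale that would need streaming, which is out of scope.
* The oracle grades from ground truth; inter-grader variability is modeled
  only as integer Gaussian noise on the 0–5 scale.
* The comparison is one AL run against the mean of 3 RL batches, as in the
  reference design; it inherits that design's limited power.
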