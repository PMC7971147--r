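---
title: "Methods: models, training and uncertainty in bioimagedl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, training and uncertainty in bioimagedl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model overview

`bioimagedl` is a configuration-driven pipeline for four standard
biomedical image-analysis tasks: binary **semantic segmentation**,
**instance segmentation**, **pixel-wise regression** (in-silico staining)
and **image classification**. One JSON file with at most twelve
user-settable parameters drives a full run: data import and normalization,
a 20 % validation split, optional online augmentation, Adam training with
early stopping, test-set prediction, optional Monte-Carlo-dropout
uncertainty, and automatic quantitative evaluation.

Segmentation and regression use an encoder–decoder U-Net in which every
convolution is zero-padded, so the output has exactly the input's spatial
shape, and every encoder block (and the bottleneck) contains a dropout
unit. The padded convolutions make the network usable on arbitrary image
sizes (inputs whose sides are not divisible by `2^depth` are zero-padded
and the output cropped back); the encoder dropout exists primarily so that
dropout can be *re-enabled at inference time* for uncertainty estimation.
The segmentation head is a sigmoid, giving per-pixel foreground
probabilities in (0, 1) that are binarized with Otsu's method; the
regression head is linear and trained with mean squared error.
Classification uses a residual network with dropout added after each
residual stage and before the final dense layer; the canonical 50-layer
bottleneck layout (`"resnet50"`) is available, and a reduced-depth
basic-block layout (`"resnet_lite"`, 18 weight layers) is the default so
that training completes in CPU-minutes.

The networks, their backward passes and the Adam optimizer are implemented
in the package itself, with the convolution, pooling and component-labeling
kernels in C++ (RcppArmadillo). This keeps the whole pipeline
self-contained and CPU-runnable; the design goal is a faithful, compact
training stack, not peak throughput.

# The twelve pipeline parameters

| parameter | JSON key (alias) | default | meaning |
|---|---|---|---|
| task | `task` (`use_algorithm`) | — (mandatory) | one of the four tasks |
| data path | `data_path` (`path`) | — (mandatory) | project folder with `train/`, `test/` |
| seed | `seed` | 1 | seeds *every* random stream of the run |
| pre-trained weights | `pretrained_weights_path` | none | weight archive for transfer learning |
| batch size | `batch_size` (`batchsize`) | 1 | samples per optimization step |
| epochs | `epochs` (`Iterations_Over_Dataset`) | 100 | upper bound; early stopping may end sooner |
| augmentations | `augmentations` | `[]` | operator names, applied online |
| loss | `loss_name` (`loss_function`) | by task | bce / cce / mse / instance composite |
| classes | `n_classes` (`num_classes`) | 2 | semantic segmentation supports exactly 2 |
| resize | `resize_to` (`image_size`) | none | spatial resize at import |
| uncertainty | `compute_uncertainty` | false | Monte-Carlo dropout after prediction |
| evaluation | `auto_evaluate` | true | quantitative evaluation after prediction |

Only the task and the data path are mandatory. Everything else has the
default above, chosen to mirror the plain run-it-with-two-settings usage
the pipeline is designed around. An optional `advanced` block carries
extension settings (network size, learning rate, Monte-Carlo pass count,
augmentation parameter ranges, ...); unknown keys at either level are
rejected rather than silently ignored, since a typo in `batchsize` that
falls back to a default is a hard-to-find bug.

# Data conventions

Input and ground-truth images pair by *identical filename* (including the
extension, case-sensitive) in `train/image` vs `train/groundtruth`;
classification labels live in `groundtruth/labels.csv` with columns
`filename,label`. Pairing failures name the offending file instead of
silently dropping it. TIFF (8/16/32-bit, single- or multi-page) and PNG
are read; multi-page TIFFs become `(Z, H, W)` stacks. Stacks are processed
slice-wise, with the z-dimension treated as extra samples during training
and reassembled at prediction time; a true 3D-convolution variant is not
implemented (it would double the compiled kernel surface without being
exercised by any of the package's desk-scale use cases).

Normalization is per-image min-max to [0, 1] by default. Per-image scaling
is the right default for heterogeneous microscopy sources whose absolute
intensities are not comparable; for intensity-comparable studies the
`advanced$normalization = "fixed"` switch divides by the dtype ceiling
instead. A constant image maps to all zeros.

The validation split holds out `max(1, round(0.2 n))` samples — the
`max(1, .)` guarantees a non-empty validation set, which early stopping
needs. Split membership is a pure function of the sorted identifiers, the
fraction and the seed, so it is invariant to directory enumeration order.

# Online augmentation

Spatial operators (horizontal/vertical flip, zoom, rotation) apply the
identical geometric map to the image and to image-valued labels; labels are
resampled nearest-neighbour and re-binarized so masks stay strictly {0, 1}.
Color operators (contrast, brightness, Poisson noise, feature scaling,
mean/std normalization, resampling, gamma shift) touch the image only —
regression *targets* are never color-transformed, a deliberate choice: the
target is the quantity to be predicted, and perturbing it would corrupt the
regression problem itself.

The operators are named, but their ranges are free choices; the defaults
are conservative enough to preserve label validity: flips with p = 0.5,
rotation uniform in ±20°, zoom in [0.9, 1.1], additive brightness ±0.1,
contrast factor [0.8, 1.25], gamma in [0.7, 1.4], Poisson noise at a
photon scale of 255, down/up resampling factor in [1, 2]. Every enabled
operator is included independently with probability 0.5 (overridable per
operator), and each drawn transform is a plain serializable list, which is
what `save_augmented_examples()` writes out for visual inspection.

# Training, early stopping, checkpointing

Training uses Adam (learning rate 1e-4, betas 0.9/0.999 by default).
Early stopping monitors the *validation loss* — the quantity the optimizer
actually optimizes, rather than a task metric — with patience
`max(5, epochs/10)` and minimal improvement 1e-5; the best-epoch weights
are restored and checkpointed. Losses: `mse` is the element mean of
squared differences; the cross-entropies clip probabilities at 1e-7 before
logarithms. The instance-composite loss reduces to binary cross-entropy
for the reference instance backend (below), whose mask head *is* a
semantic network. A non-finite loss aborts immediately, naming the epoch
and batch.

The end-to-end examples in the test suite and the acceptance script train
on 100 synthetic 64×64 images with 30 held-out test images. At this size
the default depth-3, base-16 U-Net trains in a few CPU-minutes:
8 epochs at learning rate 1e-3 for segmentation, 18 epochs at 3e-3 for
regression, and 12 epochs at 1e-3 for the reduced classifier. These
schedule settings are passed explicitly in the configurations (the
conservative 1e-4 default is tuned for long fine-tuning runs at batch
size 1, the explicit higher rates for from-scratch training on small clean
synthetic data). The depth-3/base-16 default itself is a deliberate
CPU-scale choice: a depth-4/base-32 U-Net is strictly larger than the
blob-scene tasks require and several times slower, and both are settable
per run through `advanced$unet_depth` / `advanced$unet_filters`. No batch
normalization is used anywhere: the pipeline's default batch size is 1,
where batch statistics are degenerate, and He initialization plus Adam
train these depths reliably without it.

# Instance segmentation backend

The instance pathway is specified as a contract — detect each object,
return one binary mask, bounding box and confidence per instance, sorted
by confidence — and the package ships the reference desk-scale backend:
semantic U-Net → Otsu threshold → connected components (8-connectivity in
2D, 26 in 3D), with per-component bounding boxes and confidence equal to
the mean predicted foreground probability inside the component. Components
with confidence below 0.5 are discarded, which is what makes a blank input
yield an empty instance set instead of noise components. A
region-proposal detector (Mask-RCNN style) would satisfy the same
contract but is out of scope at desk scale. `masks_from_semantic()`
implements the companion algorithm that turns binary semantic ground truth
into per-instance masks; its components are guaranteed pairwise disjoint
with union equal to the input foreground.

# Otsu thresholding

Otsu's threshold is computed per image on a 256-bin histogram spanning the
prediction's own value range — per-image rather than global, so the
binarization adapts to calibration drift between images. The threshold is
the interior bin edge maximizing the between-class variance, with class
statistics accumulated from exact per-bin value sums (not bin centers), so
the result agrees with an exhaustive pixel-level search over all 255
edges. A constant map is defined to produce an all-background mask.

# Monte-Carlo-dropout uncertainty

At inference, dropout is re-enabled and `T = 20` stochastic forward passes
are drawn (configurable via `advanced$mc_passes`). For image tasks the
uncertainty map is the per-pixel *population standard deviation* across
passes and the scalar summary `u` is the mean of that map; the standard
deviation is the conventional epistemic summary for Monte-Carlo dropout,
and the map is computed shifted against the first pass so that identical
passes give an exactly-zero map. For classification the score is the
*normalized predictive entropy* of the mean softmax vector,
`H(p̄)/log K ∈ [0, 1]`: zero for a repeated one-hot prediction, one for a
uniform mean — matching the intended anchors (0 = certain, 1 = maximally
uncertain) exactly. The distribution of scores for correct vs incorrect
predictions can be compared with a two-sided Mann–Whitney rank test
(`compare_uncertainty_distributions()`).

# Evaluation

For image tasks the per-image table contains Jaccard index (binary tasks),
pixel accuracy, mean absolute error, mean relative error
(`|p−t|/(|t|+1e−8)`) and pixel-wise Pearson correlation; aggregates are
the median and 25/75 percentiles. Two conventions are worth stating:
empty-vs-empty Jaccard is defined as 1 (perfect agreement on absence), and
a constant truth makes the Pearson correlation undefined, reported as
`NA` rather than raising. Classification adds the confusion matrix
(rows = truth), macro Jaccard of the hard assignment, MAE/MSE against
one-hot targets, and ROC/AUC via threshold sweep and the trapezoidal rule
(macro one-vs-rest beyond two classes).

Metric distributions are estimated by subsample bootstrap: 100 rounds,
each drawing half the test set *without replacement* and recording the
median. This follows the sampling-half-of-the-test-set protocol (a
subsample, not a classical with-replacement bootstrap) and is reproducible
from its seed and invariant to input ordering. Figures (side-by-side
panels, signed over/under-prediction error maps, metric boxplots,
confusion matrix, ROC) are rendered to PNG, and every figure has a numeric
CSV/JSON sibling so downstream analysis never parses images.

# Synthetic fixtures: what they do and do not show

The fixture generator plants bright, roughly disk-shaped "nuclei"
(1–6 per image, radius 4–9 px, foreground 0.8 on background 0.2, Gaussian
noise sd 0.08, 64×64) with analytically exact masks; by default blobs are
kept disjoint with a 2 px gap so instance counts are unambiguous. The
regression target is a Gaussian ridge (σ = 1.5 px) along each blob
boundary — a nuclear-envelope-like ring computed from the noiseless
geometry, so a deterministic input→staining mapping exists. Classification
shifts the blob-count range between classes by `separation`;
`separation = 0` makes the classes identically distributed by
construction. Out-of-distribution inputs are emulated by severity-scaled
blur + contrast inversion + noise (`corrupt_images()`), with severity 0
defined as bitwise identity.

Passing on these fixtures demonstrates that the machinery — pairing,
augmentation, optimization, thresholding, instance extraction, uncertainty
and evaluation — is wired correctly and can learn a known mapping. It does
*not* demonstrate performance on real microscopy: the fixtures have no
uneven illumination, no texture inside objects, no touching-object
ambiguity, no annotation noise, and far less class imbalance than real
data. Numbers obtained on them are upper bounds of convenience, not
benchmarks.

# Numerical and design notes

* Weight archives store a flat name→tensor map with a shape header in one
  RDS container; transfer matching is by layer (kernel + bias together),
  loaded only on exact name+shape agreement, and the manifest of loaded
  and skipped layers is echoed into the logfile. Matching at layer rather
  than tensor granularity prevents a layer from ending up with a
  transferred kernel but an untransferred bias.
* All randomness flows through R's global RNG, seeded once per run;
  validation splitting and the bootstrap additionally use local,
  argument-seeded streams so their results depend only on their inputs.
* Where the spatial-geometry primitives are standard (resize, rotation,
  Gaussian blur), the package calls EBImage; component labeling is
  in-package because 8/26-connectivity labeling for 2D/3D is not provided
  there.
* The logfile ends in a JSON footer (config echo, seed, per-epoch losses,
  weight manifest, per-epoch batch order, output inventory), which is what
  makes bitwise reproducibility of reruns testable.

# Known limitations

Single-channel or few-channel 2D images and z-stacks only (no DICOM/NIfTI,
no tiled slide-scale reading); slice-wise 3D handling; no batch
normalization; no learning-rate schedules or mixed precision; the
heavyweight region-proposal instance backend is a contract, not an
implementation; uncertainty is epistemic-only (no deep ensembles, no
calibration post-processing).
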