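---
title: "Segmenting surgical tools with GridMask-augmented U-Nets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting surgical tools with GridMask-augmented U-Nets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gridunet)
```

## The problem

In minimally invasive and robot-assisted surgery, the endoscopic video feed
is the surgeon's window into the operating field. Locating the instruments in
that feed, pixel by pixel, supports tool tracking, skill assessment and
eventually 3-D localisation. The task is binary semantic segmentation —
instrument versus tissue — under conditions that make it hard: instruments
are thin, elongated and articulated, they enter from the image borders, they
are frequently occluded by tissue, blood splashes or other tools, and
foreground pixels are a small minority of every frame.

`gridunet` implements a complete CPU pipeline for this task: a structured
erasure augmentation (GridMask), a conventional joint augmentation stack, two
encoder-decoder architectures, class-balanced training under a cyclical
learning rate, overlap-based evaluation, and a synthetic scene generator that
lets everything run end to end without any external imagery.

## GridMask

GridMask regularises training the way dropout regularises a layer, but
spatially and with structure. A binary mask $M \in \{0,1\}^{H\times W}$ is
multiplied into the input image,

$$\tilde X = X \times M,$$

where $M$ is a periodic lattice described by four numbers $(r, d, \delta_x,
\delta_y)$: $d$ is the side of one square unit in pixels, $r \in (0,1]$ the
keep-ratio, and $(\delta_x, \delta_y)$ the offset of the first intact unit
from the image boundary. Within each unit a square of side

$$s = \operatorname{round}\big((1 - r)\,d\big)$$

anchored at the unit origin is zeroed, so the asymptotic kept fraction is
$1 - (s/d)^2$. Unlike Cutout or random erasing, the removed pixels form
uniformly distributed, disconnected squares — the model always retains
context around each hole, and every region of the object is eventually
hidden across epochs. For a segmentation model this directly rehearses
occlusion: the network must infer tool pixels it cannot see.

```{r gridmask-demo}
m <- generate_mask(grid_spec(r = 0.5, d = 4), 8, 8)
m
mean(m) # kept fraction: 1 - (2/4)^2
```

Design choices worth stating explicitly:

* **Drop square at the unit origin, offsets translate the pattern.** The
  convention gives a closed-form kept fraction that the test suite checks
  exactly whenever $d$ divides both sides, and a brute-force tiling
  enumerator confirms every cell in randomised configurations.
* **Rotation without artefacts.** A rotated lattice is generated on a canvas
  of side $\lceil \sqrt2 \max(H, W) \rceil$, rotated with nearest-neighbour
  sampling (so the mask stays exactly binary), then centre-cropped; the
  enlarged canvas guarantees no un-tiled corners leak into the crop.
* **Labels are not masked by default.** Erasure teaches robustness only if
  the supervision still demands the full tool, so `mask_labels` defaults to
  off; the flag exists because augmentations are otherwise applied jointly
  to image and label, and a user may want the symmetric behaviour.
* **Application probability 0.5, constant over training.** A fixed Bernoulli
  draw per sample is the simplest policy consistent with "augment some
  samples, keep some clean"; it is configurable.
* **Defaults `r = 0.6`, `d` uniform in [8, 24]** for the 64-px synthetic
  frames used throughout (about a third of the short side, scaled from the
  common choice for full-resolution video frames). These are configuration
  defaults, not claims about any particular dataset.
* GridMask runs **after** intensity normalisation and after the standard
  augmentations, immediately before the encoder.

## Standard augmentations

The conventional stack — rotation, flips, scaling, translation, elastic
deformation, brightness shift, noise injection, cropping — is applied before
GridMask. All geometric transforms are composed into a single inverse
coordinate map shared by image and label: the image is resampled bilinearly,
the label with nearest-neighbour, so the pair never desynchronises and the
label stays strictly binary. Elastic deformation uses a uniform random field
smoothed with a Gaussian of configurable scale and normalised to a peak
amplitude in pixels. Photometric transforms touch only the image.
Out-of-bounds regions are filled with 0 (background). Flips are implemented
as pure index reversals so that a flip applied twice is exactly the
identity, and a fully disabled configuration is exactly the identity.

## Architectures

Both variants are encoder-decoder networks with two 3×3 convolution + ReLU
units per resolution level, 2×2 max pooling between encoder levels,
nearest-neighbour upsampling followed by a 3×3 convolution in the decoder,
and a 1×1 classification head. Channel width doubles per level from
`base_channels`.

The `"unet"` baseline uses plain convolutions, dilation 1 everywhere and
concatenation skips. The `"enhanced"` variant adds:

* **Dilated encoder.** Per-level dilation rates default to doubling at the
  two deepest levels (`1, 1, 2, 4` at depth 4), widening the receptive
  field with no extra parameters or downsampling. `receptive_field()`
  computes the analytic field from the standard recurrence
  $rf' = rf + (k_{\mathrm{eff}} - 1)\,j$ with
  $k_{\mathrm{eff}} = k + (k-1)(\mathrm{dil}-1)$.
* **Residual skips.** Encoder features pass a 1×1 projection and are
  *added* to the decoder stage, rather than concatenated.
* **Adaptive feature fusion.** When enabled, the merge is gated:
  $g = \sigma(\mathrm{conv}_{1\times1}([\mathrm{enc}, \mathrm{up}]))$ and
  the fused features are $g \odot \mathrm{enc} + (1-g) \odot \mathrm{up}$ —
  a per-channel, per-position convex combination. This is the minimal
  learned-gate realisation of "adaptively weighing" the two streams.
* **Depthwise separable convolutions.** Each 3×3 convolution becomes a
  depthwise 3×3 plus a pointwise 1×1, cutting per-layer parameters from
  $k^2 C_{in} C_{out}$ to $k^2 C_{in} + C_{in} C_{out}$.

Layer counts and widths are configuration (`depth`, `base_channels`), not
fixed constants. Downsampling by max pooling and upsampling by
nearest-neighbour + convolution are deliberate conservative choices where
the design space was open. A multi-modal fusion stage is not implemented:
the pipeline is single-modality RGB.

The forward and backward passes run through compiled (RcppArmadillo)
kernels — im2col + GEMM convolutions with dilation, depthwise convolutions,
pooling and upsampling — under a small reverse-mode tape. The analytic
gradients are verified against central finite differences in the test
suite, which is the strongest correctness check available for hand-built
backpropagation.

## Training

* **Class-balanced loss.** Weighted softmax cross-entropy per pixel; weights
  default to inverse dataset-level class frequencies normalised to sum to
  $K$, computed once over the training split. On scenes with a few percent
  foreground this upweights the instrument class roughly tenfold, which is
  the point: the loss must not be dominated by easy background pixels.
* **Cyclical learning rate.** Triangular schedule between `base_lr = 1e-4`
  and `max_lr = 1e-2`, the standard bounds for U-Net training under CLR;
  cycle length defaults to two epochs of steps. The optimiser is SGD with
  momentum 0.9 — CLR's native setting.
* **Order of operations** per sample: standard augmentation, then GridMask,
  then forward/backward. Frames are visited in a fresh random order per
  epoch; all randomness flows from the single config seed, so training is
  bit-reproducible.

## Evaluation

`confusion()` produces exact per-class TP/FP/FN/TN pixel counts;
`mean_iou()`, `mean_dsc()` and `balanced_accuracy_fg()` derive the headline
metrics

$$\mathrm{IoU}_k = \frac{TP_k}{TP_k + FP_k + FN_k},\qquad
  \mathrm{DSC}_k = \frac{2\,TP_k}{2\,TP_k + FP_k + FN_k},$$

averaged over $K = 2$ classes, plus balanced accuracy
$(\mathrm{TPR} + \mathrm{TNR})/2$ with the instrument as positive class —
the "(TPR+TNR)/2" reading is a documented decision, as "balanced accuracy
(foreground)" admits no other standard formula. A class absent from both
prediction and truth scores 1 (empty-union convention), preventing 0/0 and
keeping all-background frames from penalising a correct model.
`evaluate_model()` reports both frame-averaged (**macro**, the default
headline) and count-pooled (**micro**) aggregations, since published
tables are typically frame-averaged while pooled counts are more stable on
small test sets.

## The synthetic scenes

`generate_scene()` emulates the statistical structure of endoscopic
instrument frames rather than their appearance in detail: a smoothly
textured reddish background (two octaves of Gaussian-smoothed noise mapped
to tissue hues); one or more metallic gray tools rendered as capsule-shaped
shafts entering from the borders — biased towards the bottom corners, where
instruments enter real endoscopic views — with a bent articulated tip,
edge-darkened shading and optional specular streaks; optional
tissue-coloured occluders drawn over tools (never removed from the label);
and red splash-like blobs. Default geometry (2 tools, widths 4–8 px,
lengths 0.4–0.9 of the short side on 64-px frames) keeps the foreground
fraction in roughly 0.05–0.25 — the class imbalance that motivates the
balanced loss — and every scene is a pure function of its seed, down to the
PNG bytes written by `generate_dataset()`.

What the generator does *not* emulate: motion blur, smoke, lens distortion,
inter-frame correlation, real instrument texture and real tissue
deformation. Passing the in-package experiments therefore demonstrates that
the pipeline learns and that GridMask does not harm robustness on
structured occlusions; it does not certify performance on real surgical
video.

## Problem sizes of the in-package experiments

The shipped experiments are sized for a single CPU: the learning experiment
trains the depth-4, base-8 enhanced network (about 22k parameters) on 200
synthetic 64×64 scenes for 10 epochs and checks held-out macro mean DSC ≥
0.85; the GridMask A/B robustness comparison trains on 120 scenes for 8
epochs, 3 seeds per arm, and evaluates on a 40-scene test set with ~30% of
tool pixels occluded. On this scale the A/B answers a directional question —
GridMask must not cost robustness on occluded scenes; the two arms come out
statistically indistinguishable — not the magnitude of improvement
reported on real surgical video, which requires real data and much longer
training.

## Numerical and degenerate-input notes

* Masks and labels are validated to be strictly {0, 1}; images must be
  finite and are clipped to [0, 1] after photometric transforms.
* `r = 1` produces an all-ones mask; keep-ratios small enough that
  $s = d$ produce all-zeros masks. Both are legal.
* Inputs to the networks must have sides divisible by $2^{depth-1}$; this
  is checked, not silently padded.
* The class-weight computation floors frequencies at $10^{-6}$, so a class
  absent from the training split receives the maximum (capped) weight
  instead of an infinite one.
* All stochastic components draw from the R random stream exclusively;
  there is no hidden seed state in the compiled code.

## Known limitations

* Single-sample batching in the compiled kernels (gradients are accumulated
  over the batch in R); adequate at desk scale, not tuned for large inputs.
* No GPU path, no pre-trained encoders (training from scratch is
  deliberate), no multi-modal fusion, no MixUp/CutMix, no
  foreground-restricted GridMask.
* Inference timing is not benchmarked or claimed anywhere: it is
  hardware-bound and out of scope.
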