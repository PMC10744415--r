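# gridunet

Binary semantic segmentation of surgical instruments in endoscopic frames,
built around **GridMask** structured-erasure augmentation and an **enhanced
U-Net**. Everything — augmentation, network, training, evaluation, data —
runs on a single CPU in plain R with compiled (RcppArmadillo) kernels, and a
synthetic surgical-scene generator makes the whole pipeline exercisable with
no external data.

## What it implements

**GridMask.** An input image is multiplied by a periodic binary lattice,

```
X~ = X × M,   M ∈ {0,1}^{H×W}
```

described by four numbers `(r, d, δx, δy)`: unit side `d`, keep-ratio `r`,
and the offset of the first intact unit. Within every `d × d` unit a square
of side `round((1 − r)·d)` is zeroed, so the kept fraction tends to
`1 − (1 − r)²`-style closed forms that the test suite verifies exactly.
Random per-sample `d`, offsets and lattice rotation are drawn by a training
policy. Dropping structured, disconnected squares — rather than one large
region — rehearses partial occlusion while always leaving local context, the
regime surgical tools actually live in.

**Architectures.** A plain U-Net baseline (concatenation skips) and an
enhanced variant with a dilated deep-context encoder, residual 1×1-projected
additive skips, learned adaptive feature fusion
(`g·enc + (1−g)·up`, `g = σ(conv1×1)`), and depthwise separable
convolutions (`k²·Cin + Cin·Cout` parameters instead of `k²·Cin·Cout`).
Forward and backward passes are hand-verified against finite differences.

**Training & evaluation.** Class-weighted cross-entropy (inverse-frequency
weights, so the rare instrument class is not drowned out), SGD with momentum
under a triangular cyclical learning rate between `1e-4` and `1e-2`, a
standard joint image/label augmentation stack (rotation, flips, scale,
translation, elastic deformation, brightness, noise, crop) applied before
GridMask, and evaluation by mean IoU, mean Dice (DSC) and balanced accuracy
with the instrument as positive class, in both frame-averaged (macro) and
count-pooled (micro) aggregation.

## Worked example

```r
library(gridunet)

# 1. a GridMask lattice: r = 0.5, d = 4 on an 8x8 canvas keeps 75%
m <- generate_mask(grid_spec(r = 0.5, d = 4), 8, 8)
mean(m)
#> [1] 0.75

# 2. synthetic surgical scenes: tools over tissue, small foreground
train_set <- generate_scenes(scene_config(), 200, seed = 1)
mean(sapply(train_set$masks, mean))   # foreground fraction ~ 0.11

# 3. train a small enhanced network with GridMask in the loop
model <- build_model(model_config("enhanced", depth = 4, base_channels = 8),
                     seed = 1)
parameter_count(model)
#> [1] 22128
fit <- train_model(model, train_set,
                   train_config(epochs = 10, seed = 1,
                                augment = augment_config(
                                  rotation_deg = 15, hflip_prob = 0.5,
                                  brightness_delta = 0.1, noise_sd = 0.02)))
tail(fit$history, 1)
#>    epoch      loss  accuracy  mean_dsc
#> 10    10 0.0840489 0.9508728 0.9103103

# 4. evaluate on fresh scenes
evaluate_model(fit$model, generate_scenes(scene_config(), 50, seed = 5001))
#> Segmentation metrics over 50 frames (macro / micro):
#>   mean IoU:               0.8570 / 0.8585
#>   mean DSC:               0.9199 / 0.9213
#>   balanced accuracy (fg): 0.9598 / 0.9601
```

The trained model reaches a macro mean Dice of about 0.92 on held-out
synthetic scenes: the per-pixel overlap between predicted and true
instrument masks, averaged over the two classes and over frames. Balanced
accuracy near 0.96 says the model is almost equally right on the scarce
instrument pixels as on the abundant background.

A command-line wrapper (`inst/cli/gridunet`) exposes the same pipeline as
`synth`, `augment-preview`, `train` and `eval` subcommands driven by a YAML
configuration; see `?main`.

## Package layout

- `R/gridmask.R` — lattice construction, mask application, sampling policy
- `R/augment.R` — joint geometric/photometric augmentation stack
- `R/model.R`, `R/nn.R`, `src/kernels.cpp` — architectures, tape autograd,
  compiled conv/pool/upsample/loss kernels
- `R/train.R`, `R/metrics.R` — CLR, balanced loss, training loop, metrics
- `R/synthdata.R` — synthetic scene generator, dataset I/O, occluded variant
- `R/config.R`, `R/cli.R` — YAML run configuration and CLI
- `vignettes/gridunet-methods.Rmd` — the model, the design decisions and
  what the synthetic experiments do and do not show
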