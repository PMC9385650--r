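---
title: "Confidence-gated two-stream cascades: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Confidence-gated two-stream cascades: model, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(cascadenet)
```

## The problem and the model

Clinical image classifiers are usually a single convolutional network
applied uniformly to every image, even though most images are easy and only
a minority — typically those whose diagnostic evidence is a small lesion —
need high-resolution, high-capacity processing. `cascadenet` implements a
dynamic two-stream cascade for this setting:

1. **Small stream.** Every sample is resized to a low resolution and scored
   by a small staged convolutional classifier. A stream is a stem
   convolution, a sequence of residual stages (the familiar basic and
   bottleneck residual units, with batch normalization), global average
   pooling and a single linear layer; class probabilities are
   `softmax(f(block_K ∘ … ∘ block_1(X)))`.
2. **Routing.** If the maximum softmax probability exceeds a threshold τ
   (strictly), the small stream's label is accepted and computation stops.
   Otherwise the prediction is considered unreliable and the sample is
   escalated.
3. **Large stream with feature reuse.** Escalated samples are re-encoded
   from the original image at a higher resolution and scored by a larger
   stream. The two streams have the same number of stages, and a feature
   reuse module (FRM) links each pair of same-index stages: the small
   stream's stage-i tap is bilinearly upsampled to the large stream's
   stage-i spatial size, passed through a 1×1 convolution that aligns
   feature domains (and channel counts), and added pointwise to the large
   stream's stage-i output, which then feeds stage i+1 (for the last stage,
   the pooled head). The small stream therefore runs exactly once per
   sample, and its intermediate features are reused rather than discarded.

Expected compute per sample is `c_small + ρ·(c_large + c_FRM)`, with ρ the
escalation fraction; the cascade trades accuracy against cost through τ
alone.

## Training protocol

Training is two-step, as in the study the package reproduces:

* **Stage 1.** Both streams are trained independently with cross-entropy
  under Adam (defaults: learning rate 1e-4, batch 16, 300 epochs each, at
  224/336 px), each at its own input resolution, with horizontal flips,
  vertical flips, random cropping and per-channel normalization.
* **Stage 2.** The FRM weights are created at zero — so the fused large
  stream starts exactly at the trained large stream's behavior — and the
  large stream plus FRM weights are fine-tuned (default 50 epochs) while
  the small stream stays frozen. Freezing keeps the routing behavior fixed
  between stages; it is also why escalation statistics measured after
  stage 1 remain valid afterwards.

Where the protocol leaves choices open the package takes the standard ones
and records them here: cross-entropy loss (the standard pairing with a
softmax head); no learning-rate schedule (a single rate is stated); random
crop realized as an area fraction in [0.8, 1] followed by a resize to the
stream resolution; normalization defaulting to the widely used
natural-image channel statistics; escalated samples always take the large
stream's label even if its confidence is lower; argmax ties broken toward
the lowest class index. The `pretrained_init` flag exists for completeness
but errors when enabled: no pretrained weights are shipped and downloading
is out of scope.

## Cost accounting

`count_macs()` counts one multiply–accumulate per kernel element per output
element of every convolution (projection shortcuts included) and `in × out`
for the linear head; pooling, normalization and elementwise operations are
excluded, and biases are ignored in the operation count. Published cost
tables for these architectures are commonly stated at approximately *half*
the standard multiply–accumulate total, so the counter exposes two labeled
conventions: `"standard-mac"` and `"paper-half"` (exactly half). Under
`"paper-half"` the three reference streams at their published resolutions
come out at 0.907, 4.19 and 4.68 ×10⁹ against published values of 0.91,
4.21 and 4.73 ×10⁹ — within 1.2% everywhere; the residual gap presumably
reflects the original counting tool's treatment of auxiliary operations.
`frm_cost()` counts only the 1×1 alignment convolutions, consistent with
the same conventions.

## The synthetic data generator

`generate_dataset()` emulates the *statistical structure* the cascade
exploits — difficulty correlated with the resolution required — not the
appearance of real endoscopy:

* **Easy stratum** (default 70%): the class is encoded globally, as a
  class-specific background hue under a random low-frequency illumination
  field plus Gaussian pixel noise. The cue survives any downsampling a
  stream would apply.
* **Hard stratum**: the background is class-uninformative (neutral gray,
  random gentle illumination gradient) and the class lives entirely in one
  small lesion-like blob (default radius 3 px in a 96 px image) placed
  uniformly inside a margin, so crops retain it. Inside the blob a fine
  radial ring texture encodes the class by its radial phase (8 phases for
  8 classes). Three properties are engineered in: the texture is
  *flip-invariant* (flips are part of the augmentation protocol, so an
  orientation cue would corrupt labels); its disc-mean is subtracted, and
  its cycle length (max(1.5, r/2) px) sits just above the pixel scale, so
  block averaging below the lesion scale destroys it; and lesion centers
  sit on integer pixels, so the per-class stamp is exact and a
  template-matching oracle can certify separability.

`stratum_bayes_accuracy()` is that oracle: it classifies fresh Monte-Carlo
samples using the generator's own cue parameters (nearest background color
for easy; normalized correlation against the class ring templates at the
known lesion center for hard). At the defaults it measures easy accuracy
1.0 at every resolution, hard accuracy 1.0 at full resolution, and hard
accuracy 0.07–0.22 (chance 0.125) once the image is resized to a third or
a quarter of its size — the designed resolution gap the cascade needs.

What passing tests on this generator do **not** show: robustness to
device-specific artifacts, patient-level correlation between images,
class-imbalanced clinical priors, or lesions whose difficulty is semantic
rather than resolution-bound. Real laryngoscopy data remains necessary for
clinical claims.

## Desk-scale profile and numerical choices

The package's tests exercise a desk-scale profile (`desk_profile()`) chosen
once to fit routine CPU runs: the tiny 24/96 px stream pair (stage channels
16/32, the large stream one unit deeper), 480 synthetic images split 70/30,
learning rate 1e-3, batch 16, 60 + 10 epochs. Four desk-profile choices deserve explanation,
because each one is load-bearing for learning a radius-3 lesion that
occupies ~0.3% of a 96² image under global average pooling:

* **Normalization layers.** Streams carry a normalization layer after
  every convolution (`stream_spec(norm=)`). The reference specs use batch
  normalization, the published residual-network choice (batch statistics
  during training, running averages at evaluation, so inference is
  deterministic and batch-independent). The tiny *large* stream instead
  uses instance normalization — per-sample, per-channel standardization,
  identical in training and evaluation. The distinction matters when
  batches mix strata of very different contrast: with batch statistics,
  the high-variance easy images dominate every channel's scale and the
  low-contrast lesion signal stays diluted below Adam's reach (the
  training loss demonstrably sits at the chance plateau for tens of
  epochs); per-sample statistics amplify the lesion relative to each
  image's own background regardless of batch composition, and the same
  configuration then learns from the first epoch.
* **Per-image input normalization.** The desk profile standardizes each
  image to zero mean and unit variance jointly over its three channels
  (`normalize = "per-image"`), rather than subtracting fixed channel
  constants. Joint standardization preserves color direction — the easy
  stratum's cue — while equalizing overall contrast, so the low-contrast
  hard images are not structurally quieter than easy ones. The paper-scale
  profile keeps the conventional fixed channel statistics.
* **Flips-only augmentation at desk scale.** The random crop's bilinear
  resampling shifts the synthetic ring texture off the pixel grid and
  empirically prevents the large stream from learning the hard stratum at
  all; the full protocol (crop included) is kept in `paper_profile()`,
  where the cue of interest is not a near-Nyquist synthetic texture.
* **Epoch budget.** Stage 1 runs long enough for the large stream to pass
  the slow emergence of lesion-texture features (its loss declines
  smoothly but the hard stratum only resolves after tens of epochs);
  stage 2 then needs only a few epochs from the zero-FRM starting point.

Other numerical choices: He-normal weight initialization (deterministic per
seed, caller's RNG untouched); batch-norm ε = 1e-5, momentum 0.1;
probability vectors validated to |Σp − 1| ≤ 1e-4 before routing; bilinear
interpolation uses half-pixel centers with edge clamping, and the FRM only
upsamples; odd intermediate resolutions (336/32 is not an integer) are
handled with the standard floor arithmetic, and a spec is rejected only
when a stride-2 layer would receive fewer than 2 pixels; all randomness in
a run flows from the single run seed.

## Known limitations

* Training is plain Adam without weight decay, schedules or early
  stopping; at paper scale users would likely want all three. No
  validation split is carved out during training — streams train on the
  full training split, and the routing threshold is tuned by sweeping
  `sweep_tau()` on that same split afterwards.
* One feature reuse module is attached per stage by default; models with
  links at a subset of stage indices are supported (`NULL` entries in
  `frm_links`), but the shipped fine-tuning always trains the full set.
* The spatial dimensions of odd-sized stages make the quadratic
  cost-vs-resolution rule exact only at resolutions divisible by the total
  stride.
* The escalated path recomputes the image encoding at the large resolution
  from the original image; no activations are shared across resolutions
  beyond the FRM taps, exactly as in the method being implemented.
* Checkpoints are R-native RDS files; bit-exact reproduction is guaranteed
  within one platform/BLAS, not across.
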