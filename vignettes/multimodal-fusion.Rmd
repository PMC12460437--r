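---
title: "Multi-scale interaction networks for multi-modality image fusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-scale interaction networks for multi-modality image fusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmfuse)
```

## The problem

Infrared–visible and medical image fusion combine two co-registered views of
one scene into a single image that keeps the complementary strengths of both:
the infrared (or MRI-like) modality carries salient targets that survive poor
lighting but lacks texture and colour, while the visible (or CT/PET-like)
modality carries fine texture that is easily destroyed by darkness or
overexposure. The failure mode this package targets is exactly that
interaction: bright headlight glare or dark shadow in the visible channel
swallowing targets that the other modality sees perfectly well.

`mmfuse` implements an end-to-end fusion network built around one organising
idea: features at different pyramid depths should interact differently.
Shallow features are detail carriers and are fused by local spatial
attention; deep features are semantic carriers and are fused by global
cross-attention; and a dedicated gate reconciles the two kinds of
information inside the decoder.

## The network

Each modality passes through its own encoder of `depth` 3×3 convolutions
(stride 1 first, stride 2 afterwards, ReLU throughout), giving feature maps
at scales 1, 1/2, ..., 1/2^(depth−1). The default is the four-level pyramid
(1, 1/2, 1/4, 1/8): going deeper erodes original-scale edge information
faster than it adds semantic context, while stopping at three levels weakens
the global context available to the deep interaction.

At every level a junction fuses the two modality features:

* **Shallow levels (1–2) — spatial-attention block.** The two feature stacks
  are concatenated; channel-wise max and mean compress the stack into two
  maps; a 3×3 convolution plus sigmoid turns them into a two-channel spatial
  attention map. Each modality is residually re-weighted by its own channel
  (`F + F·att`), then fused channel-by-channel: channel *a* of each modality
  forms a pair that one group of a 3×3 grouped convolution (C groups, 2→1
  channels each) reduces to one output channel. Grouping keeps the
  interaction per-channel and avoids cross-channel interference.
  The choice of one attention channel per modality (rather than a single
  shared map) follows the two-channel shape of the attention tensor; a
  `sfim_shared_gate` switch implements the shared reading.
* **Deep levels (3+) — cross-attention block.** Both features are
  downsampled (factor 2 by default), projected by 3×3 convolutions into
  per-modality keys and values, and a single query is projected from the
  channel concatenation of both, so the query carries complementary
  attributes of the two modalities. Row-softmax attention `softmax(Q·Kᵀ)`
  gives each modality a global context that is upsampled back, residually
  added, concatenated and reduced by a 3×3 convolution. The attention logits
  are used exactly as written, without a 1/√d temperature; a
  `scaled_attention` flag is available but off by default. Attention is
  single-head.
* **Decoder.** Starting from the deepest fused map, each decoder applies a
  1×1 convolution, a 3×3 convolution and a bilinear ×2 upsample
  (half-pixel-centre convention, i.e. corner alignment disabled), merging
  with the next-shallower fused map. At the level-2 junction the merge is
  the deep–shallow interaction gate: `F_deep + F_shallow · σ(GAP(F_deep))`,
  a parameter-free channel gate in which deep semantics decide how much of
  each shallow detail channel to pass. All other merges are concatenation +
  3×3 convolution. The final head is four 3×3 convolutions, ReLU on the
  first three and Tanh on the last, with `(x+1)/2` mapping the output into
  `[0, 1]`.

Disabling any of the three interaction blocks (`enable_sfim`,
`enable_psim`, `enable_fim`) replaces that junction by concatenation + 3×3
convolution, which is the ablation baseline family.

## The training objective

Training minimises `L_total = L_text + λ·L_int` with λ = 5.

* **Masked intensity loss.** A salient-object mask (from the ground-truth
  labels) and a contrast mask (pixels whose squared deviation from the local
  9×9 box mean exceeds 0.02) are added; wherever the sum is positive the
  infrared mask `m_ir` is 1. The visible mask is the complement
  `m_vi = 1 − m_ir`: the published description of the visible mask is
  ambiguous, and complementarity makes the loss a well-posed partition —
  each pixel is pulled toward exactly one source, which is what suppresses
  overexposed visible regions. `L_int` is the per-pixel L1 distance to the
  mask-selected source, averaged over the image.
* **Texture loss.** `L_text` is the mean L1 distance between the Sobel
  gradient magnitude of the fused image and the element-wise maximum of the
  two source magnitudes. Magnitude is `|Gx|+|Gy|` (the common fusion-loss
  convention, cheaper and subgradient-friendly; a Euclidean option exists
  for the array-side function), with reflective borders.
* **Ablation variants.** `loss_variant = "pixel"` replaces the masked term
  by the plain two-source L1; `"max"` pulls the fused image toward the
  element-wise source maximum; `"no_texture"` drops the texture term.

Optimisation is SGD with momentum 0.9 (momentum is unstated in the protocol
this mirrors; 0.9 is the conventional default and is configurable) at a
constant learning rate of 1e-3 (a cosine schedule is available). The
`"full"` profile keeps the published protocol — 256 px crops, widths
32/64/128/256, batch 8, 300 epochs. The `"desk"` profile used by the tests
and the acceptance script scales this to 32 px patches, widths divided by 4,
batch 4, and a few hundred steps, so every run finishes in minutes on one
CPU; the network is identical in structure.

Because no deep-learning framework is assumed, the package carries its own
reverse-mode differentiation engine over plain arrays: convolutions are
im2col gathers followed by BLAS matrix products, and every operator used by
the network has a hand-written adjoint. The engine is validated against
central finite differences in the test suite.

## The synthetic phantom generator

The generator emulates the statistical structure of the target failure mode
with analytically known ground truth:

* modality 1 — a dark, smoothly varying background plus `n_hot_objects`
  bright, low-texture elliptical blobs (the salience carrier); the union of
  the ellipse supports is the ground-truth salient label, so by construction
  the mean intensity inside the label exceeds the mean outside;
* modality 2 — an RGB image sharing the scene geometry, carrying
  band-limited high-frequency texture (correlation length `texture_scale`,
  default 3 px), with the salient objects slightly darkened ("submerged")
  and a contiguous `overexposure_fraction` (default 10%) of the area
  saturated at exactly 1.0 on all channels.

Defaults (3 hot objects, 10% overexposure, noise SD 0.02) were chosen once
as a plausible desk-scale analogue of night-time road scenes: a handful of
warm targets, visible glare covering an appreciable fraction of the frame,
and mild sensor noise. Ellipse-based objects were chosen because they give
exact masks and controllable overlap without any segmentation step.

What the phantoms do **not** emulate: real sensor point-spread functions and
modality-specific noise statistics, parallax or registration error (inputs
are assumed aligned, as in the deployment setting), semantic structure
(vehicles, pedestrians), and natural-image statistics. A model that learns
on phantoms demonstrates that the architecture and losses behave as designed
— salience preserved, texture transferred, saturation suppressed — not that
it reaches benchmark-level quality on real data; that requires the real
training corpora.

## The metric suite

Seven standard fusion-quality metrics are pinned to concrete formulations,
since the literature cites them without formulas:

* **EN** — Shannon entropy of the 256-bin histogram, in bits.
* **AG** — mean of `sqrt((dx²+dy²)/2)` over forward differences.
* **SF** — `sqrt(RF²+CF²)` of RMS row/column differences.
* **SSIM** — 11×11 Gaussian window (σ 1.5), K1 = 0.01, K2 = 0.03, dynamic
  range 1, valid-window averaged; the fusion value is the mean against the
  two sources (whether one source, both, or a weighted mix is meant is
  unspecified in the literature; the two-source mean is the symmetric
  choice).
* **SCD** — sum of Pearson correlations of (fused − one source) with the
  other source; a zero-variance operand contributes 0 by convention.
* **Q_abf** — Sobel edge strength and orientation per image, per-source
  preservation through the canonical sigmoidal strength/orientation models
  (Γ_g = 0.9994, κ_g = −15, σ_g = 0.5; Γ_α = 0.9879, κ_α = −22, σ_α = 0.8),
  weighted by source edge strength. Each sigmoid is normalised by its value
  at perfect preservation so that a perfect fusion scores exactly 1 — with
  the raw constants a perfect fusion scores ≈ 0.975, which would make the
  upper bound of the metric implementation-dependent.
* **VIF** — pixel-domain multi-scale Gaussian-scale-mixture formulation
  (four scales, windows 17/9/5/3 with σ = size/5, noise variance 2 on the
  0–255 range), computed source-as-reference against the fused image and
  averaged over the two sources.

Numeric parity with published benchmark tables is explicitly not claimed:
those numbers depend on external datasets and unspecified metric
implementations. The suite is internally validated against closed forms and
independently coded references.

## Numerical choices and degenerate inputs

* Convolutions zero-pad by 1 so the stated scale arithmetic is exact; inputs
  to the full network must be divisible by 2^(depth−1), and the inference
  path edge-pads and crops back otherwise.
* Bilinear resampling uses the half-pixel-centre convention everywhere, so
  ×1/2 downsampling is exactly 2×2 block averaging.
* Channel-wise max pooling breaks ties by first index; softmax subtracts the
  row maximum before exponentiation.
* Rotation augmentation is restricted to multiples of 90° so labels never
  need interpolation; flips and crops are drawn once per sample and applied
  identically to both modalities and the label.
* Colour handling is full-range BT.601: the network fuses luminance only and
  the chroma planes pass through exactly (the fused RGB is clipped only at
  file-writing time, keeping the pass-through bit-exact in memory).
* All randomness (phantoms, initialisation, batch order, augmentation) runs
  in private RNG streams derived from explicit seeds; a seed plus a
  configuration determines every artifact bit-exactly.

## Problem sizes

The test suite and the acceptance script use 32 px phantoms with
quarter-width networks for training (200 SGD steps, batch 4), 64 px phantoms
for held-out evaluation (the smallest size the four-scale VIF pyramid
accepts comfortably), brute-force oracle comparisons at up to 8×8×4, and a
12–20-step budget per configuration in the ablation harness. These sizes
were chosen as the smallest at which the learning signal (loss decrease,
trained-beats-untrained, salience preservation) is stable across seeds.

## Known limitations

* The desk-scale profile demonstrates mechanism, not benchmark quality;
  reproducing published benchmark numbers requires the external datasets and
  the full training schedule.
* The deep cross-attention is quadratic in the number of downsampled
  positions; the full profile at 256 px keeps attention grids at 16×16 and
  8×8, but very large inputs would need a larger `psim_downsample`.
* The decoder-side interaction gate uses the channel gate only; the
  accompanying prose description of that block also mentions spatial
  attention without defining it, and the defined form is what is
  implemented.
* 16-bit output is TIFF-only (PNG writing is 8-bit); 16-bit PNG reading
  works.
* Checkpoints are R serialisations with an explicit version tag, not a
  cross-language format.
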