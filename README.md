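# mmfuse — multi-scale interaction networks for multi-modality image fusion

`mmfuse` fuses co-registered image pairs from two modalities — infrared +
visible, or MRI-like + CT/PET/SPECT-like — into one informative image. It is
aimed at researchers in biological and medical image analysis who need a
fully self-contained, CPU-trainable fusion pipeline: the package ships the
network, its training objective, a synthetic phantom generator with exact
ground truth (so no external dataset is required), a seven-metric
fusion-quality evaluator, and a command-line interface.

## The model

Two encoder paths extract feature pyramids F₁ⁱ, F₂ⁱ at scales 1, 1/2, 1/4,
1/8 (four 3×3 convolutions each, stride 1 then 2). Each level is fused by an
interaction block:

* **Shallow levels — spatial attention + grouped fusion.** With F_max, F_avg
  the channel-wise max/mean of the concatenated stack,

  F̂ₓ = Fₓ ⊕ (Fₓ ⊗ σ(Conv([F_max, F_avg])))

  gates each modality by its own channel of a two-channel sigmoid map; the
  enhanced features are then fused channel-by-channel by a 3×3 grouped
  convolution (C groups, 2→1 channels per group).

* **Deep levels — shared-query cross-attention.** Downsampled features give
  per-modality keys/values Kₓ, Vₓ and one query Q projected from the
  channel concatenation of both modalities; Aₓ = softmax(Q·Kₓᵀ) routes a
  global context Aₓ·Vₓ back to each modality before a convolutional merge.

* **Decoder — deep–shallow gate.** At the level-2 junction,

  F′ = F_deep ⊕ (F_shallow ⊗ σ(GAP(F_deep))),

  a parameter-free channel gate in which deep semantics select shallow
  detail channels. The head maps a Tanh output affinely into [0, 1].

Training minimises **L_total = L_text + λ·L_int** (λ = 5): a Sobel texture
loss against the element-wise maximum of the source gradient magnitudes,
plus a masked intensity loss in which a salient-object mask ∪ high-contrast
mask selects the infrared source and its complement selects the visible
source — the mechanism that suppresses overexposed visible regions.

Because the R ecosystem has no deep-learning runtime dependency here, the
package includes its own reverse-mode differentiation engine over plain
arrays (im2col + BLAS); it is finite-difference-validated in the test suite.

## Worked example

```r
library(mmfuse)

# six synthetic training scenes: hot elliptical targets on a dark background
# (modality 1) against a textured, partly overexposed RGB scene (modality 2)
pairs <- lapply(1:6, function(i)
  generate_phantom_pair(phantom_config(height = 32, width = 32, seed = 1000 + i)))

cfg <- fusion_config(profile = "desk", seed = 1)   # 32 px patches, widths 8/16/32/64
state <- train(cfg, pairs, steps = 200)

mean(state$history$l_total[1:20])          # mean loss, first 20 steps
#> [1] 1.790662
mean(tail(state$history$l_total, 20))      # mean loss, last 20 steps
#> [1] 0.955433

# fuse a held-out phantom and score it
p  <- generate_phantom_pair(phantom_config(height = 64, width = 64, seed = 1501))
vi <- rgb_to_ycbcr(p$img2)$y
fused <- fuse_images(p$img1, vi, state)
round(evaluate_all(fused, p$img1, vi), 4)
#>      vif     ag    scd   qabf     sf     en   ssim
#> 1 0.1099 0.0721 1.5873 0.3358 0.1312 7.3925 0.3654

mean(fused[p$salient_label == 1])           # salience preserved ...
#> [1] 0.8722
mean(vi[p$salient_label == 1])              # ... where the visible is dark
#> [1] 0.2611
```

The loss halves within 200 desk-scale SGD steps; the fused image keeps the
bright salient blobs of modality 1 (mean 0.87 over the ground-truth salient
mask, against 0.26 in the visible modality) while carrying the visible
texture, which is what the SSIM/Q_abf gains over an untrained network
quantify. With an RGB second modality, `fuse_images()` fuses the
luminance only and passes Cb/Cr through exactly.

The CLI wraps the same functions:

```sh
Rscript inst/cli/mmfuse.R synth --out phantoms --n 8 --seed 1 --height 48 --width 48
Rscript inst/cli/mmfuse.R train --data phantoms --out model.rds --seed 1
Rscript inst/cli/mmfuse.R fuse  --img1 a_m1.png --img2 a_m2.png --ckpt model.rds --out fused.png
Rscript inst/cli/mmfuse.R eval  --fused fused/ --src1 m1/ --src2 m2/ --csv report.csv
Rscript inst/cli/mmfuse.R ablate --steps 20 --depths 3,4,5 --out ablation.csv
```

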