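# wristseg

Edge-based lesion segmentation for 2-D wrist MRI-like images, built for
image-analysis work where the anatomy of interest — carpal bones and the
distal radius — shares nearly identical gray levels, cartilage shows up as
thin crescents, and acquisitions carry noise plus a smooth multiplicative
bias field. The package is aimed at researchers who need a fully
reproducible, testable implementation of this classic pipeline rather than
a black box: every stage is a from-scratch, oracle-tested implementation
with exact synthetic ground truth.

## What it implements

1. **Canny edge detection** — Gaussian smoothing
   (G(x,y) = e^{−(x²+y²)/2σ²}/2πσ², truncated at ⌈3σ⌉, renormalized),
   finite-difference gradients (D = √(gx²+gy²), θ = atan2(gy, gx)),
   4-sector non-maximum suppression with a strict tie rule, and
   double-threshold hysteresis: strong pixels (D ≥ t_h) seed, weak pixels
   (t_l ≤ D < t_h) survive only if 8-connected to a strong pixel.
2. **Particle swarm optimization** — the bare global-best update
   V ← wV + c₁ρ₁(pbest − H) + c₂ρ₂(gbest − H), H ← H + V, with box
   clipping and velocity clamping; used to tune the SVM.
3. **Kernel SVM** — the soft-margin dual
   max Σκᵢ − ½ΣΣ κᵢκₛgᵢgₛK(aᵢ,aₛ) s.t. Σκᵢgᵢ = 0, 0 ≤ κᵢ ≤ C, solved by a
   compiled SMO-style maximal-violating-pair solver; RBF kernel
   e^{−γ‖a−b‖²}; PSO tunes (log₁₀C, log₁₀γ) by cross-validated accuracy.
   Edge pixels are described by 7 local features and classified
   lesion/non-lesion; the positive contour is closed and filled into a
   mask.
4. **Quality battery** — PSNR, MSE, Pratt FOM (ρ = 1/9), SSIM, edge
   continuity (CI) and credibility (BI) indices, and Acc/Sen/Spe/Dice from
   pixelwise confusion counts.
5. **Phantom generator** — wrist-like synthetic images (gray-matched
   convex bones, a thin crescent, a contrast lesion, polynomial bias
   field, Gaussian or Rician noise) with exact truth edges and lesion
   masks, so the whole pipeline is testable without patient data.

See `vignettes/wrist-phantom-segmentation.Rmd` for the full model
description and design rationale.

## Worked example

```r
library(wristseg)

# a default 128x128 wrist phantom (noise sigma 0.03, bias amplitude 0.1)
ph <- generate_phantom(default_wrist_spec(seed = 1))

# Canny edges at the default high/low threshold ratio 1.8
edges <- canny_detect(ph$image, canny_params(sigma = 1.5, t_l = 0.02, ratio = 1.8))
sum(edges)                              # 546 edge pixels
edge_continuity(edges)                  # 0.9982 (nearly closed contours)
edge_credibility(edges, ph$truth_edges) # 1 (all detected pixels near truth)

# held-out benchmark: train PSO-SVM on 5 phantoms, segment 5 unseen ones
bm <- run_benchmark(n = 10, config = pipeline_config(seed = 1))
bm$summary
#>    metric          mean        sd
#>  1 psnr        26.5     0.511
#>  2 mse          0.00227 0.000272
#>  3 fom          0.565   0.00909
#>  4 ssim         0.891   0.00155
#>  5 ci           0.997   0.00154
#>  6 bi           1       0
#>  7 accuracy     0.999   0.0000926
#>  8 sensitivity  1       0
#>  9 specificity  0.999   0.0000937
#> 10 dice         0.951   0.00362
glance(bm$tuning)   # tuned C = 0.704, gamma = 49.5, CV accuracy = 1
```

Reading the output: PSNR/MSE/SSIM compare the Gaussian-smoothed noisy
phantom against its noise-free rendering (denoising fidelity); CI/BI score
the detected edge maps (closed, truth-coincident contours); accuracy,
sensitivity, specificity and Dice compare the reconstructed lesion masks
with ground truth on held-out phantoms — a mean Dice of 0.951 means the
predicted lesion overlaps the true lesion almost completely.

`autoplot(ph)`, `plot_edges(ph$image, edges)`, `autoplot(bm)` and the
`tidy()`/`glance()` methods give ggplot2 figures and tibble summaries of
every result type.

## Command line

A thin CLI over the same functions is installed with the package:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "wristseg.R", package = "wristseg"))')
Rscript $CLI simulate --seed 5 --out-dir ph5
Rscript $CLI detect --input ph5/image.tif --sigma 1.5 --tl 0.02 --ratio 1.8 --out edges.png
Rscript $CLI sweep --seed 5 --out sweep.csv
Rscript $CLI benchmark --n 10 --seed 1 --out benchmark.json
```

Subcommands: `simulate`, `detect`, `train`, `segment`, `evaluate`,
`sweep`, `benchmark`.

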