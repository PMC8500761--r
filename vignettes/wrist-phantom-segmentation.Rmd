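---
title: "Edge-based lesion segmentation for wrist MRI-like images: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Edge-based lesion segmentation for wrist MRI-like images: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 5)
library(wristseg)
```

## The problem

Wrist MRI slices are hard to segment automatically: the carpal bones
(scaphoid, lunate) and the distal radius have very similar gray levels,
cartilage appears as thin crescents, and acquisitions carry noise plus a
smooth multiplicative intensity inhomogeneity (bias field). `wristseg`
implements an edge-based segmentation pipeline for such images: a Canny
detector extracts candidate edges, a kernel SVM — with its penalty factor
and kernel width tuned by particle swarm optimization (PSO) — classifies
each edge pixel as lesion or non-lesion, and the positive edge set is
closed and filled into a lesion mask. Because no public wrist cohort is
available, the package ships a synthetic phantom generator with exact
ground truth; every stage is tested against it.

## The pipeline

### Canny edge detection

1. **Gaussian smoothing.** The image is convolved with the isotropic kernel
   $G(x, y) = \frac{1}{2\pi\sigma^2} e^{-(x^2+y^2)/2\sigma^2}$, truncated at
   radius $\lceil 3\sigma \rceil$ and renormalized to sum to one. Borders
   use symmetric reflection, so constant images are preserved exactly and
   the mean is conserved.
2. **Gradient field.** Central differences in the interior, one-sided at
   borders; magnitude $D = \sqrt{g_x^2 + g_y^2}$ and direction
   $\theta = \operatorname{atan2}(g_y, g_x)$.
3. **Non-maximum suppression (NMS).** $\theta$ is quantized to four sectors
   (0°, 45°, 90°, 135°); a pixel keeps $D$ only if strictly greater than
   both neighbors along the gradient direction. The strict-both tie rule
   means constant fields produce no edges; its one quirk is that a
   perfectly symmetric step whose magnitude profile peaks equally on two
   adjacent pixels is suppressed entirely — any real (noisy) image breaks
   such ties.
4. **Double-threshold hysteresis.** Pixels with $D \ge t_h$ are strong;
   pixels in $[t_l, t_h)$ are weak and kept only when 8-connected to a
   strong pixel through weak/strong pixels; everything below $t_l$ is
   discarded. With $t_h = r\, t_l$ and $r \le 1$ the double threshold
   degenerates to a single threshold at $t_l$, which the ratio-sweep
   experiment exploits.

Thresholds are absolute values on the suppressed magnitude by default.
Because the absolute gradient scale of an arbitrary image is unknowable in
advance, `canny_params(relative = TRUE)` also accepts $t_l$ as a fraction
of the maximum suppressed magnitude.

### Particle swarm optimization

The swarm follows the bare global-best update
$$V \leftarrow w V + c_1 \rho_1 (\mathrm{pbest} - H) + c_2 \rho_2 (\mathrm{gbest} - H), \qquad H \leftarrow H + V,$$
with $\rho_1, \rho_2$ uniform on $[0, 1]$ per particle and dimension.
Two deliberate choices:

* **Inertia.** The default is $w = 1$ (no damping), the bare update above.
  Undamped swarms explore but do not converge finely, so a configurable
  inertia with optional linear decay is exposed; internal consumers (the
  SVM tuner and the convergence tests) use $w: 0.9 \to 0.4$, a standard
  schedule in the PSO literature. Velocities are clamped to the box width
  and positions clipped to the box (the clipped velocity component is
  zeroed) as divergence safeguards.
* **$\rho$ distribution.** Uniform on $[0,1]$ — the standard choice for a
  random factor confined to that interval.

### Kernel SVM

Training solves the soft-margin dual
$$\max_\kappa \; \sum_i \kappa_i - \tfrac12 \sum_{i,s} \kappa_i \kappa_s g_i g_s K(a_i, a_s)
\quad \text{s.t.} \quad \sum_i \kappa_i g_i = 0, \; 0 \le \kappa_i \le C,$$
by an SMO-style maximal-violating-pair solver written in C++ (closed-form
two-variable subproblems, first-order working-set selection, stopping when
the maximal KKT violation falls below `tol`). The box constraint
$\kappa_i \le C$ is the soft-margin form: a hard margin admits no penalty
factor, and a penalty factor is exactly what the PSO stage tunes. The
offset $o^*$ averages $g_i - \sum_s \kappa_s g_s K(a_s, a_i)$ over free
support vectors. The decision rule is
$f(a) = \operatorname{sgn}\!\big(\sum_i \kappa_i^* g_i K(a_i, a) + o^*\big)$
with $\operatorname{sgn}(0) = +1$. Kernels: RBF
$e^{-\gamma\|a-b\|^2}$ (default; the usual choice for PSO-SVM pipelines)
and linear (kept for analytic tests — the two-point problem has the exact
solution $u^* = (1,0)$, $o^* = -1$, $\kappa^* = (1/2, 1/2)$).

**Edge features.** No canonical per-edge-pixel descriptor exists for this
pipeline, so the package uses a minimal, local, orientation-aware vector of
seven components per edge pixel: windowed mean and standard deviation of
the intensity, gradient magnitude, $\cos\theta$, $\sin\theta$, and the
normalized row/column position. Window 5×5, reflect-padded.

**Hyperparameter tuning.** `pso_svm_tune()` minimizes
$1 - \text{CV accuracy}$ ($k$-fold, stratified, fold assignment fixed by
the seed) over $\log_{10} C \in [-2, 4]$ and
$\log_{10}\gamma \in [-4, 2]$. Everything is deterministic given the seed.

**From edge labels to a mask.** Predicted-positive edge pixels form a
(possibly broken) contour; a 5×5 morphological closing bridges small gaps
and hole filling produces the lesion mask. Closing and filling are
delegated to EBImage. The 5×5 brush is a compromise: 3×3 fails to bridge
two-pixel contour gaps that noise regularly produces, larger brushes
inflate the mask boundary.

### Quality metrics

* $\mathrm{MSE} = \frac{1}{hl}\sum (f - \hat f)^2$ and
  $\mathrm{PSNR} = 10\log_{10}(pe_{\max}^2 / \mathrm{MSE})$ (dB; $+\infty$
  sentinel for identical images, serialized as `null` in JSON).
* Pratt figure of merit
  $\mathrm{FOM} = \frac{1}{\max(\hat X, X_{\text{ideal}})} \sum_{\hat c}
  \frac{1}{1 + \rho \hat d^2}$ with $\rho = 1/9$, the conventional scaling.
* SSIM: brightness × contrast × structure with unit exponents, constants
  $(0.01L)^2$, $(0.03L)^2$, $C_3 = C_2/2$, uniform 8×8 windows, unit
  stride — the conventional parameterization.
* Edge continuity CI: edge segments are 8-connected components; for
  segment $i$ with $n_i$ pixels, $SE_i$ is the fraction of its pixels with
  at least two 8-neighbors in the segment (endpoints of open curves and
  isolated pixels count against continuity);
  $\mathrm{CI} = \sum n_i SE_i / \sum n_i$, capped just below 1 to respect
  the index's $[0, 1)$ range. This neighbor-degree definition is an
  explicit design choice — the index is otherwise underdetermined — and is
  isolated behind `edge_continuity()` so alternatives can be swapped.
* Edge credibility BI: fraction of detected edge pixels within Chebyshev
  distance 1 of a truth edge pixel; likewise a design choice isolated
  behind `edge_credibility()`.
* Diagnostics: Acc, Sen, Spe, DSC from pixelwise confusion counts, with
  `NA` sentinels for empty denominators.

## The phantom generator

`default_wrist_spec()` emulates the features that make wrist slices hard:

* three convex "bone" regions with deliberately similar means (0.55, 0.58,
  0.62 — pairwise gaps ≤ 0.07, mimicking gray-matched radius/scaphoid/
  lunate);
* one thin crescent ("cartilage", thickness well under a tenth of the
  image width);
* one lesion: a small ellipse inside the radius, +0.25 above its host
  (edema-like contrast);
* a second-order polynomial multiplicative bias field rescaled to
  $[1 - A, 1 + A]$ (default $A = 0.1$, a typical visually-apparent level of
  gray unevenness);
* additive zero-mean Gaussian noise, default $\sigma = 0.03$ on a $[0,1]$
  scale (a mid-quality acquisition); a Rician option exists because
  magnitude MRI noise is Rician, but Gaussian is the default — at SNRs
  away from the air background the two are close, and the Gaussian null is
  what the variance-recovery test checks.

Geometry is jittered by the seed (±2 px centers, ±1 px axes) so phantoms
differ across seeds while remaining comparable; rasterization uses
pixel-center point-in-shape tests with painter's-order overwriting. Truth
edges are pixels whose region label differs from a 4-neighbor; the lesion
mask is the lesion region itself. Defaults were fixed once, from the above
rationale, and are not tuned per experiment.

What the phantom does **not** emulate: partial-volume blur at boundaries,
k-space/motion artifacts, anatomical shape variability, multi-slice
context, textured marrow. Passing the benchmark therefore demonstrates
correctness and robustness of the pipeline under controlled noise and
bias, not clinical performance.

## Experiments

* **Ratio sweep** (`sweep_ratio()`): edge maps at
  $t_h/t_l \in \{0.3, 0.6, 0.9, 1.2, 1.5, 1.8\}$ at fixed $t_l$, scored by
  CI/BI and edge count. Edge count is provably non-increasing in the ratio;
  ratios ≤ 1 collapse to the single-threshold detector. The sweep reports —
  it does not hard-code any ratio as optimal, though 1.8 is the package
  default.
* **Held-out benchmark** (`run_benchmark()`): $n$ phantoms (default
  128×128); the first half trains (pooled labelled edge features, capped at
  300 per class; PSO-tuned $C, \gamma$; final SVM), the second half is
  segmented and scored. Training labels mark edge pixels within Chebyshev
  distance 1 of the truth lesion boundary as positive. Per-phantom
  self-training is deliberately rejected — held-out evaluation is the
  defensible protocol when none is prescribed. The PSNR/MSE/SSIM reference
  is the noise-free, bias-free rendering of the same geometry and the
  "processed" image is the Gaussian-smoothed noisy phantom, so those three
  metrics measure denoising fidelity while FOM/CI/BI and the diagnostic
  scores measure edge and mask quality.

Problem sizes (128×128 phantoms, $n = 10$, 10-particle/12-iteration tuner,
3 folds, 300 training pixels per class) were chosen so a full benchmark
runs in about a minute on a single core while leaving the solver and the
swarm non-trivial work; they are package defaults, not protocol claims.

```{r benchmark, eval = FALSE}
bm <- run_benchmark(n = 10, config = pipeline_config(seed = 1))
bm$summary
```

## Numerical choices and degenerate inputs

* Kernel truncation at $\lceil 3\sigma \rceil$ with renormalization;
  reflect padding everywhere (no spurious border edges).
* NMS strict-both tie rule (see above); direction sectors closed on the
  left.
* `hysteresis_link` requires $0 < t_l \le t_h$; `canny_detect` maps
  $r < 1$ to the single-threshold degenerate case rather than erroring.
* SMO stopping tolerance $10^{-8}$ on the maximal KKT violation (training
  defaults; the tuner uses $10^{-6}$ for speed), iteration cap with a
  convergence check that only aborts when the residual violation is
  materially large ($> 10^{-3}$).
* Empty edge maps: features are a zero-row tibble; CI/BI of empty maps are
  0; FOM of an empty detected map is 0; an empty ideal map is a validation
  error.
* All-black images yield empty edge maps, empty masks, and exit cleanly.
* Seeds: one master seed; every stage derives a named substream
  (`phantom<i>`, `bias`, `noise`, `folds`, `swarm`, `subsample`), so runs
  are bit-reproducible and stages independently reseedable. Derived seeds
  stay below $2^{31}$.

## Known limitations

* The feature-extraction role sometimes attributed to PSO in edge-based
  PSO-SVM pipelines has no defined objective; here PSO only tunes
  $(C, \gamma)$. Wrapper-style feature selection is not implemented.
* Class imbalance between lesion and non-lesion edge pixels is handled
  only by stratified folds and the per-class training cap.
* Binary classification only; no multi-class lesion typing, no probability
  calibration, no 3-D volumes, no DICOM.
* CI and BI rest on package-chosen definitions (neighbor degree;
  distance-1 coincidence); both are isolated behind their functions.
* Canny conventions (4-sector NMS without interpolation, reflect borders)
  legitimately differ from other implementations; agreement with them is
  structural, not pixel-exact.
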