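---
title: "Methods: diffusion denoising, repulsive snakes, and morphometric classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diffusion denoising, repulsive snakes, and morphometric classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nodemorph)
```

nodemorph analyses lymph nodes in 2-D CT slices in three stages:
edge-preserving denoising, active-contour segmentation, and morphometric
classification. This vignette records the models behind each stage, the
parameters that matter, and the design decisions taken where more than one
reasonable construction exists.

## 1. Edge-enhanced nonlinear diffusion

CT slices are noisy, and the boundary detail of a node — exactly what
morphology-based staging relies on — is what generic smoothing destroys
first. The denoiser evolves the image $u(x, t)$ from the observation $I$
under

$$u_t \;=\; \mu\,\mathrm{div}\!\left(g(|\nabla G_{\sigma_0}\!*u|)\,\nabla u\right)
\;-\; \frac{|\nabla u|}{\max|\nabla u|}\,(u - I),$$

with no-flux (homogeneous Neumann) boundary conditions. The first term is
anisotropic diffusion: the edge-stopping function $g$ shuts smoothing down
where the (Gaussian-regularised) gradient is large. The second term is an
*adaptively weighted* fidelity term: its weight $|\nabla u|/\max|\nabla u|$
is near 1 on edges — pinning $u$ to the observed image precisely where
structure lives — and near 0 in flat regions, where diffusion is free to
remove noise. This differs from a constant-$\lambda$ fidelity
(Rudin–Osher–Fatemi), which applies the same pull everywhere.

Choices the model itself leaves open, fixed as follows:

* **Edge-stopping function.** $g(s) = 1/(1 + (s/k)^2)$ (the rational
  Perona–Malik form) by default, with the total-variation form
  $g(s) = 1/(s + \varepsilon)$ selectable via
  `diffusion_params(g = "tv")`. Both families are established; the
  rational form is bounded at $s = 0$ and interacts more gracefully with
  an explicit scheme.
* **Contrast parameter.** `contrast_k = NULL` sets $k$ per image to the
  90th percentile of $|\nabla G_{\sigma_0}\!*I|$, a standard automatic
  choice that adapts to the image's gradient distribution.
* **Fidelity normaliser.** $\max|\nabla u|$ is recomputed every iteration
  over the whole image; if it is zero (constant image) the weight is
  defined as 0, making constant images exact fixed points.
* **Discretisation.** Explicit forward Euler, central differences, and
  conservative half-grid fluxes (the diffusivity between two pixels is the
  mean of their cell values). With edge replication this makes pairwise
  fluxes cancel exactly, so the pure diffusion operator conserves the
  image mean to machine precision and satisfies a discrete maximum
  principle for $g \le 1$ and `time_step` $\le 0.25$ (the 2-D explicit
  stability bound; default 0.2). The TV baseline additionally clamps its
  step to $0.25/\max g$ and $1/\lambda$ per iteration, since its
  diffusivity is unbounded near zero gradient.
* **Defaults** (`diffusion_params()`): `mu_diff = 1`, `sigma0 = 1` px,
  `n_iterations = 50`. Intensities are processed as real values
  throughout; quantisation happens only when writing PNG.

The package carries the comparison baselines the denoiser is evaluated
against — Perona–Malik (no fidelity, no gradient regularisation),
explicit TV/ROF, exact median filtering, and a bilateral filter — plus a
Canny implementation (Sobel gradient, non-maximum suppression,
8-connected hysteresis) and a variance-ratio SNR,
$10\log_{10}(\mathrm{var(signal)}/\mathrm{var(noise)})$, which
round-trips with the noise generator by construction.

## 2. Repulsive-force GVF snake

Segmentation uses a closed parametric snake $C(s)$ minimising tension
$\alpha|C'|^2$, rigidity $\beta|C''|^2$, and an external energy weighted
by $\lambda$. The external force is a gradient vector flow (GVF) field
$\mathbf v = (u, v)$: the solution of

$$\mu \nabla^2 u - (f_x^2 + f_y^2)(u - f_x) = 0, \qquad
  \mu \nabla^2 v - (f_x^2 + f_y^2)(v - f_y) = 0,$$

where $f = |\nabla(G_{\sigma_0}\!*I)|^2$ is the edge map. GVF diffuses
edge-map gradients into homogeneous regions, giving the snake a capture
range far beyond the raw gradient's.

GVF has a known failure mode for lymph nodes: adjacent structures. When a
second object sits within the capture range, its (often stronger) edges
dominate the field and the snake leaks onto the neighbour even when the
initial curve correctly encircles the target. The repulsive modification
negates the field outside the initialisation region $R$:

$$\mathbf v^- = \begin{cases} \mathbf v, & \text{inside } R,\\
-\mathbf v, & \text{otherwise,}\end{cases}$$

so a neighbour's pull becomes a push back towards the legitimate
boundary. The transform preserves vector magnitude everywhere and is an
involution outside $R$ — properties the test suite asserts exactly.

Design decisions:

* **Order of operations.** Edge force map → GVF diffusion → repulsion.
  Repulsion after diffusion keeps the field inside $R$ identical to the
  plain GVF field, so the two variants differ only where the repulsion is
  meant to act.
* **$R$** is the filled interior of the user's initial contour
  (`contour_to_mask` of the initialisation).
* **Edge-map scale.** GVF is linear in $f$, so `segment_node()`
  normalises $f$ to $[0, 1]$; this puts the external force on a unit
  scale regardless of image contrast.
* **Snake solver.** Semi-implicit: internal forces through a cyclic
  banded system $(I + \gamma(\alpha K_2 + \beta K_4))^{-1}$ factorised
  once per point count, external force explicit via bilinear sampling.
  The contour is resampled to uniform arc spacing every 10 iterations and
  evolution stops when the largest vertex displacement falls below
  `convergence_tol` (default 0.05 px). Defaults: $\alpha = \beta = 0.1$,
  $\lambda = 1$, $\gamma = 1$, $\mu_{\mathrm{GVF}} = 0.2$, 200 GVF sweeps,
  at most 400 snake iterations.
* **Force normalisation.** Raw GVF vectors by default;
  `normalize_force = TRUE` switches to unit vectors. The smoothing and
  GVF trade-off parameters ($\mu$ of the diffusion stage and
  $\mu_{\mathrm{GVF}}$) are deliberately independent parameters.
* **Coordinates.** $(x, y)$ = (column, row), 1-based, pixel centres at
  integer coordinates; rasterisation uses the even-odd rule with pixel
  centres lying exactly on the polygon counted as inside (so a square
  with corners on pixel centres covers the full closed lattice square).

Multiple nodes are segmented as independent runs; the package does not
evolve coupled contours or handle topology changes.

## 3. Morphometric feature panel

`extract_features()` measures a fixed, ordered panel of 19 features per
segmented node: area, perimeter, long/short axis diameters (from the
second-moment ellipse, $4\sqrt{\lambda_i}$), axis ratio, circularity
$4\pi A/P^2$, eccentricity, extent, solidity (pixel count over rasterised
convex-hull pixel count), compactness, box-counting fractal dimension of
the boundary, boundary irregularity (perimeter over convex perimeter),
nodal density (mean intensity), heterogeneity (intensity SD), 32-bin
intensity entropy, skewness, kurtosis, edge sharpness (mean gradient
magnitude on the boundary band), and normalised radial-length variance.

The identity of the original clinical 19-feature panel is not publicly
documented; this list is the package's own reconstruction of a standard
morphology-plus-histogram panel and is a stable published contract
(`feature_names()`). It contains all seven measurements reported as
discriminative for nodal status — fractal dimension, heterogeneity,
long- and short-axis diameter, nodal density, and solidity — with
heterogeneity defined as the intensity SD (entropy kept as a separate
feature), since no formula is on record.

Numerical notes: the boundary set is the 8-connected inner boundary;
box sizes are dyadic from 2 px to a quarter of the smaller image side and
the dimension is the least-squares slope of $\log N(\varepsilon)$ vs
$\log(1/\varepsilon)$, clipped to $[1, 2]$. Because the box grid is
anchored at the image origin the estimate can move by a few hundredths
under rigid translation — inherent to box counting at finite resolution.
Perimeter is the length of the traced 8-connected boundary chain, a
known ~5 % overestimate for smooth shapes; it cancels in ratio features
and is consistent across masks. Diameters and areas scale by `spacing`
(mm/px) when provided.

## 4. Feature selection and classification

Labels are $+1$ (malignant) and $-1$ (benign). The training data are
split once, stratified 50/50 (`split_data`), into $S_1$ (fitting) and
$S_2$ (evaluation). Classifier quality during selection is tracked by two
quantities: accuracy $P$ and sensitivity $Q$, and by the two-part
stability loss

$$\mathrm{Loss} = |P(S_1) - P(S_2)| + 2\,|Q(S_1) - Q(S_2)|,$$

which is small when the classifier generalises consistently across the
split and doubly penalises unstable sensitivity.

**Backward pass.** Starting from all features: train an SVM on $S_1$,
measure each active feature's permutation importance on $S_2$ (mean
accuracy drop over `n_repeats = 20` seeded permutations of that feature's
column), and remove the least important feature, ties broken by canonical
panel order. The removal is kept only while the loss does not exceed the
best value seen so far; the first deteriorating removal is undone and the
pass stops (floor: `min_features = 2`).

**Forward pass.** The removed features are scanned and the candidate
giving the largest increase in $S_2$ accuracy is re-added, repeatedly,
stopping at the first scan with no strict improvement (ties again by
canonical order).

`select_features()` alternates the two passes until the active set is
stable between rounds (at most 10 rounds). The division of labour —
importance ranking by accuracy drop, the stopping rule by the stability
loss, forward re-addition by held-part accuracy — is this package's
resolution of a genuinely underdetermined protocol, and is documented as
such. Every stochastic step derives from the configuration seed, so
(data seed, selection seed) fully determines the selected set.

**Classifier.** An SVM (via libsvm): RBF kernel, `cost = 1`,
`gamma = "scale"` (computed as $1/(p\,\mathrm{var})$ on the standardised
training matrix the kernel actually sees), features standardised by
training-set mean/SD stored with the model. Kernel, cost, gamma, and
class weights are configurable; none were on record for the original
study. Evaluation is leave-one-out cross-validation aggregated into one
confusion table; accuracy, sensitivity and specificity follow the
confusion-table identities exactly, and a metric whose denominator class
is absent is reported as `NA`, never 0.

## 5. What the synthetic generators emulate

All validation inputs are generated in code with exact ground truth:

* `make_shapes_image()` — piecewise-constant shapes (the denoising test
  scene uses three objects of different contrasts on a 128×128 canvas)
  with per-shape masks and the exact boundary edge map;
  `add_gaussian_noise()` corrupts to a stated SNR (the protocol uses
  9.46 dB) with i.i.d. Gaussian noise.
* `make_adjacent_objects_scene()` — a low-contrast target disk 2 px from
  a larger, high-contrast distractor: the regime in which a plain GVF
  snake leaks across the gap and the repulsive force is required.
* `make_node_phantom()` — a node with a radially perturbed boundary
  (amplitude ∝ `irregularity`, area-normalised so irregular and smooth
  phantoms are compared at equal size) and i.i.d. Gaussian internal
  texture; a Koch-snowflake variant provides a boundary of known fractal
  dimension $\log 4/\log 3$ for calibrating the box-counting estimate
  (rasterised at level 4, nominal diameter 160 px on a 320 px canvas).
* `make_feature_dataset()` — labelled Gaussian feature tables with a
  known informative subset (class means at $\pm$`effect_size`$/2$, unit
  variance); the selection-recovery experiment uses n = 200, 3
  informative features at effect size 2 among 16 noise features, over 20
  dataset seeds.
* `make_phantom_dataset()` — the end-to-end analogue of a clinical
  table: phantoms drawn from overlapping class-conditional parameter
  distributions (size and mean attenuation class-independent; boundary
  irregularity and internal heterogeneity shifted between classes), with
  all 19 features measured. The LOOCV comparison uses n = 100.

What these generators deliberately do **not** model: CT physics (beam
hardening, partial-volume effects, correlated noise), 3-D structure,
anatomy around the node, and reader variability in initial contours.
Passing tests therefore establish algorithmic correctness and the
direction of the claimed effects under controlled conditions — not
clinical performance, which in the original setting was established on
pathology-verified patient data that is not distributed.

## 6. Degenerate inputs and edge cases

Constant images are fixed points of every denoiser and yield empty edge
maps and zero GVF fields. Empty masks, single-pixel masks and boundaries
of fewer than 8 pixels raise data errors; masks touching the image border
compute with a warning. A snake leaving the grid aborts with the last
valid contour attached to the error. A constant feature column has
permutation importance 0 by definition (with a warning), and LOOCV folds
that degenerate to a single training class are counted as errors, with a
warning, rather than silently dropped.

## 7. Problem sizes

The test and acceptance runs use 128×128 scenes for denoising/edge
evaluation, ≤ 9×9 grids for fixed-point verification against a Jacobi
oracle (tolerance 1e-8), a 128×128 adjacency scene, 320×320 rasterisation
for the fractal calibration, n = 200 × 20 seeds for selection recovery
and n = 100 phantoms for the LOOCV comparison — sizes at which every
stage's behaviour is already stable and the full suite runs in a few
minutes.
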