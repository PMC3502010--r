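# nodemorph

Quantitative analysis of lymph nodes in 2-D CT slices, for researchers
studying morphology-based nodal staging (e.g. in rectal cancer). Whether a
node is benign or malignant correlates with its shape and internal
structure — smooth and homogeneous versus irregular, spiculated and
heterogeneous — but measuring that reliably requires (a) denoising that
does not destroy boundary detail, (b) a segmentation that does not leak
onto adjacent structures, and (c) a feature panel pruned to the
measurements that actually discriminate. nodemorph implements all three
stages, plus the synthetic phantoms needed to validate each one against
exact ground truth.

## The methods

**Edge-enhanced nonlinear diffusion.** The image u evolves from the
observation I under

    u_t = mu * div( g(|grad(G_sigma0 * u)|) grad u )  -  (|grad u| / max|grad u|) (u - I)

with no-flux boundaries: anisotropic diffusion whose edge-stopping
function g shuts smoothing down at boundaries, plus a fidelity term whose
weight |∇u|/max|∇u| pins u to the data *only* near edges, leaving flat
regions free to denoise. Perona–Malik, TV/ROF, median and bilateral
baselines, Canny edge extraction and a variance-ratio SNR complete the
evaluation protocol.

**Repulsive-force GVF snake.** A parametric active contour driven by a
gradient vector flow field v = (u, v) solving
`mu ∇²u − (fx²+fy²)(u − fx) = 0` (and likewise for v) with
f = |∇(G\_σ0 ∗ I)|². Outside the initialisation region R the field is
negated,

    v⁻ = v  if inside R,   −v  otherwise,

so a bright neighbouring structure pushes the contour back toward its
legitimate boundary instead of capturing it — the failure mode of plain
GVF snakes on adjacent nodes.

**Morphometry + selection + SVM.** Each segmented node yields a fixed
19-feature panel (area, axis diameters, solidity, box-counting fractal
dimension, nodal density, heterogeneity, histogram statistics, ...).
Backward elimination by permutation importance — with a two-part
stability loss `|P(S1)−P(S2)| + 2|Q(S1)−Q(S2)|` (P accuracy, Q
sensitivity) as the stopping criterion — followed by greedy forward
re-addition prunes the panel; an SVM with leave-one-out cross-validation
reports accuracy, sensitivity and specificity.

## Worked example

```r
library(nodemorph)

# A noisy synthetic scene with a known node
scene <- make_shapes_image(96, 96, list(
  phantom_spec("disk", size_px = 40, base_intensity = 150,
               center = c(48, 48))), seed = 1)
noisy <- add_gaussian_noise(scene$image, snr_db = 9.46, seed = 2)

# 1) Denoise
den <- edge_enhanced_diffusion(noisy, diffusion_params())
compute_snr_db(scene$image, noisy)   # 9.43 dB
compute_snr_db(scene$image, den)     # 25.00 dB

# 2) Segment with the repulsive GVF snake
seg <- segment_node(den, initialize_contour(c(48, 48), 25, 100))
dice_coefficient(seg$mask, scene$masks[[1]])   # 0.992

# 3) Measure the 19-feature panel
fe <- extract_features(den, seg$mask)
round(fe[c("long_axis", "short_axis", "solidity",
           "fractal_dimension", "nodal_density", "heterogeneity")], 3)
#>         long_axis        short_axis          solidity fractal_dimension
#>            39.662            39.485             1.000             1.000
#>     nodal_density     heterogeneity
#>           150.147             4.941

# 4) Select features and cross-validate on a phantom cohort
tab <- make_phantom_dataset(n = 100, seed = 42)
sel <- select_features(tab, selection_config(seed = 1))
loocv(tab)$accuracy                        # 0.94  (all 19 features)
loocv(tab, sel$active_features)$accuracy   # 0.97  (selected subset)
```

The denoiser raises the SNR by ~15 dB while the segmented disk recovers
the true diameter (40 px) to within half a pixel; on the phantom cohort,
pruning the panel to the discriminative features improves leave-one-out
accuracy over using all 19.

A thin command-line wrapper over the same functions is installed at
`inst/cli/nodemorph.R`
(`Rscript nodemorph.R {denoise|edges|segment|features|simulate} ...`).

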