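# qdaseg

Slice-wise brain tumor segmentation for single-channel MRI volumes, built
around a quantum-inspired dragonfly clustering optimizer and geodesic
level-set contour refinement. The package is aimed at researchers in
medical image analysis who want a fully reproducible, dependency-light
implementation of this pipeline family that can be exercised end to end
without any imaging dataset: a seeded synthetic head phantom with
ground-truth labels ships with the package.

## The method

For each axial slice of a NIfTI volume:

1. **Preprocessing** — Otsu thresholding plus morphological closing, hole
   filling and largest-component selection strip non-head background;
   Perona–Malik anisotropic diffusion
   (`I <- I + λ Σ exp(-(∇I/κ)²) ∇I`, κ = 30, λ = 0.14, 10 iterations)
   denoises while preserving edges; masked histogram equalization enhances
   contrast.
2. **Quantum dragonfly clustering** — brain intensities are clustered into
   K = 4 tissue classes (CSF/background, grey, white, tumor). A
   deterministic k-means fit seeds a swarm of N = 20 dragonflies, each
   carrying a candidate centroid vector, updated by the five classic
   operators (separation, alignment, cohesion, food attraction, enemy
   distraction)

   ```
   ΔX_{t+1} = s·S + a·A + c·C + f·F + e·E + ξ·QCM(ΔX_t)
   X_{t+1}  = clamp(X_t + ΔX_{t+1})
   ```

   where the inertia and Lévy-flight behaviors pass through a quantum
   computing mechanism: values are quantized to a qubit
   `q = (2x − (hi+lo))/(hi−lo)` with unit-norm amplitudes, rotated by a
   2×2 rotation gate (|θ| = 0.02π, signed toward the best "food" solution),
   and dequantized. Gaussian mutation `x(1 + k·r)` (k = 1) with greedy
   acceptance preserves elitism: the best fitness never worsens and never
   exceeds the k-means seed's.
3. **Level-set refinement** — the brightest cluster (after speckle,
   border-rim and local-contrast cleanup) initializes a signed-distance
   field `Φ` (negative inside) evolved by

   ```
   Φ <- Φ + ΔT [ g·Wc·κ·|∇Φ| − g·Wa·ν·|∇Φ| + ∇g·∇Φ ],   ΔT = 1/(6·Wa·Wc)
   ```

   with edge map `g = 1/(1 + (|∇(G_σ*I)|/λ)²)`, curvature κ, and a
   deflating balloon speed ν = −0.3, until the contour locks onto the
   tumor edge. Masks are restacked into a 3D NIfTI segmentation.

Evaluation implements the standard suite: accuracy, recall, precision,
specificity, Dice `2TP/(2TP+FP+FN)`, and the 95th-percentile Hausdorff
boundary distance.

## Worked example

```r
library(qdaseg)

## fit the clustering model on a 4-component intensity mixture
set.seed(7)
px <- c(rnorm(300, 20, 8), rnorm(300, 80, 8),
        rnorm(300, 140, 8), rnorm(300, 220, 8))
fit <- qda_cluster(px, K = 4, config = qda_config(T = 50, seed = 1))
fit
#> Quantum dragonfly clustering fit
#>   K = 4 clusters over 1200 pixels; 16 swarm iterations
#>   centroids: 20.624, 79.978, 139.39, 219.9
#>   fitness (quantization error rate): 0.0253139
```

The four centroids land within half an intensity unit of the true component
means (20/80/140/220); the fitness is the mean pixel-to-centroid distance as
a fraction of the intensity range. `coef`, `predict`, `fitted`, `residuals`,
`summary` and `plot` behave as for any R model fit.

```r
## segment a synthetic head volume and score it against ground truth
ph  <- phantom_generate(phantom_spec(shape = c(240, 240, 20), seed = 1))
seg <- run_pipeline(ph$volume, pipeline_config(seed = 1))
seg
#> <qda_segmentation> 20 slices, 3 segmented, 1 tumor component(s)
#>   mask voxels: 1500

res <- evaluate_segmentation(seg$mask$data != 0, tumor_truth(ph$labels),
                             region = seg$brain_mask$data != 0)
#> Dice 0.978 | HD95 1.0 px | accuracy 0.9998 | recall 0.965 |
#> precision 0.992 | specificity 1.0000
```

Slices without brain or without a plausible tumor component are flagged and
left empty (`seg$report` holds per-slice diagnostics), and reruns with the
same seed are bit-identical.

A thin command-line interface wraps the same functions:

```sh
inst/cli/qdaseg phantom  vol.nii.gz truth.nii.gz --seed 4 --shape 240,240,20
inst/cli/qdaseg segment  vol.nii.gz seg.nii.gz   --seed 4
inst/cli/qdaseg evaluate seg.nii.gz truth.nii.gz --report report.json
```

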