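---
title: "Quantum dragonfly level-set segmentation: models, parameters and design choices"
author: "qdaseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantum dragonfly level-set segmentation: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qdaseg)
```

## The problem and the method

Gliomas and other brain tumors appear in single-channel MR images as regions
whose intensity separates them from healthy tissue, but whose borders are
irregular, low-contrast in places, and embedded in images with noise and
smooth intensity inhomogeneity. `qdaseg` segments such tumors slice by slice
in three stages:

1. **Preprocessing.** Otsu's threshold binarizes the slice; morphological
   closing, hole filling and largest-component selection produce a head/brain
   mask that is superimposed on the slice (skull stripping); Perona–Malik
   anisotropic diffusion removes noise while preserving edges; histogram
   equalization, restricted to the mask, enhances contrast.
2. **Clustering.** Brain-pixel intensities are grouped into $K = 4$ classes
   (CSF-or-background, grey matter, white matter, tumor) by k-means, whose
   centroids seed a quantum-inspired dragonfly swarm. The swarm refines the
   centroid vector; the brightest cluster is taken as the tumor and its
   boundary becomes the initial contour.
3. **Level-set refinement.** The contour, represented as the zero set of a
   signed-distance field $\Phi$ (negative inside), evolves under curvature,
   an edge-gated balloon force and an edge-attraction term until it locks
   onto the tumor boundary.

A seeded synthetic head phantom with ground-truth labels makes every stage
testable without any imaging data.

## The dragonfly swarm and its quantum mechanism

Each dragonfly $i$ carries a candidate centroid vector
$X_i \in \mathbb{R}^K$ (the scalar swarm equations apply coordinate-wise;
with one scalar per individual the clustering fitness of a single individual
would be undefined, so the full-vector encoding is used). Five operators act
on each individual given its neighbours within a growing radius:

* separation $S_i = -\sum_j (X_i - X_j)$,
* alignment $A_i = \overline{V_j}$ (the step vectors double as velocities;
  no separate velocity state exists),
* cohesion $C_i = \overline{X_j} - X_i$,
* food attraction $F_i = X_{food} - X_i$,
* enemy distraction $E_i = X_{enemy} + X_i$ (the sum, as in the original
  dragonfly formulation).

Some transcriptions of the cohesion operator carry the opposite sign,
$X_i - \overline{X_j}$, which *repels* an individual from its neighbourhood
centre and contradicts the operator's stated purpose and the
dragonfly-algorithm literature; the attracting form is the default and
`literal_cohesion = TRUE` restores the repelling one.

The step update is
$\Delta X_{t+1} = sS + aA + cC + fF + eE + \xi\,QCM(\Delta X_t)$,
followed by $X_{t+1} = \mathrm{clamp}(X_t + \Delta X_{t+1})$. The inertia
term passes through the *quantum computing mechanism*: the step is clamped
into the search bounds $[lo, hi]$, quantized to
$q = (2x - (hi+lo))/(hi-lo) \in [-1, 1]$, mapped to a unit-norm amplitude
pair, rotated by the gate
$\begin{pmatrix}\cos\theta & -\sin\theta\\ \sin\theta & \cos\theta\end{pmatrix}$,
and dequantized. Individuals with no neighbours take a Lévy flight through
the same mechanism: rotate the quantized *position*, dequantize, then add a
Mantegna Lévy perturbation scaled by the position.

Decisions the method family leaves open, fixed here once:

* **Amplitude map.** A scalar $q$ must correspond to an amplitude pair to be
  rotated. We use the smooth bijection $\beta = \sin(\pi(q+1)/4)$,
  $\alpha = \sqrt{1-\beta^2}$, inverted after rotation (with clamping of the
  rotated $\beta$ into $[0,1]$; the stored amplitude pair itself keeps exact
  unit norm, so rotations compose exactly).
* **Rotation angle.** No value is ever stated; the default magnitude is
  $0.02\pi$ with the sign chosen so the rotated amplitude moves $q$ toward
  the food solution's quantized value.
* **Fitness.** Two definitions appear: a supervised mean absolute percentage
  error (which needs ground-truth classes unavailable at segmentation time)
  and an informal "clustering error". Operationally the fitness is the mean
  absolute quantization error of the pixels against the candidate centroids,
  normalized by the intensity range — a rate in $[0,1]$. The MAPE form is
  implemented exactly and used in validation on labelled phantoms.
* **Schedules.** Inertia $\xi$ ramps $0.9 \to 0.4$; separation, alignment,
  cohesion and enemy weights follow the canonical adaptive ramp that decays
  to zero mid-run; the neighbour radius grows linearly from a quarter of the
  intensity range to the full range.
* **Mutation.** Gaussian mutation $x(1 + kr)$, $k = 1$, applied per
  individual with probability 0.1 and accepted greedily (only when fitness
  improves), which preserves the monotone best-fitness invariant.
* **Elitism.** The food position is the best solution ever seen; the enemy
  is the worst of the current population. The best-fitness history is
  therefore monotone non-increasing, and since one initial individual *is*
  the k-means seed, the final fitness can never be worse than the seed's.

## k-means seeding

Lloyd iteration on 1D intensities with deterministic seeding. Plain quantile
seeding misses the global optimum on roughly a fifth of small instances, so
the seed is instead the exact weighted dynamic-programming optimum of the
intensity histogram (exact when the data have at most 512 distinct values,
which holds for 8-bit MRI; binned otherwise). Lloyd cannot increase the
within-cluster sum of squares from there, so on discrete data the procedure
*is* globally optimal — the property the test suite asserts against
exhaustive partition enumeration. Empty clusters are repaired by relocating
the centroid to the pixel farthest from its current centroid. The reported
`objective` is the sum of absolute deviations (in intensity units); the
quantity Lloyd descends, and the one asserted monotone per iteration, is the
SSE.

## Level-set evolution

The refinement solves, explicitly in time,
$$\Phi_{t+1} = \Phi_t + \Delta T\,\big[g\,W_c\,\kappa\,|\nabla\Phi|
  \;-\; g\,W_a\,\nu\,|\nabla\Phi| \;+\; \nabla g \cdot \nabla\Phi\big],$$
with curvature $\kappa = \nabla\!\cdot\!(\nabla\Phi/|\nabla\Phi|)$ by central
differences (an $10^{-8}$ guard in the norm), Godunov upwinding of the
balloon term and sign-upwinding of the advection term. Conventions and
repairs:

* $\nu$ is the *outward* balloon speed under the inside-negative sign
  convention: positive inflates the contour, negative deflates it. The
  default $-0.3$ shrinks a slightly dilated initialization onto the tumor
  edge.
* The edge map is the standard geodesic form
  $g = 1/\big(1 + (|\nabla (G_\sigma * I)|/\lambda)^2\big)$, with
  $\sigma = 1.5$ px. $\lambda = 1$ gives the classic unnormalized variant;
  the pipeline passes $\lambda$ equal to 2% of the brain dynamic range,
  because on an 8-bit scale the unnormalized $g$ is $\sim 10^{-4}$ across
  the entire smoothed edge band and freezes all motion before the contour
  reaches the edge.
* The time step defaults to $\Delta T = 1/(6\,W_a W_c)$: a step must
  shrink, not grow, with the weights for an explicit scheme to remain
  stable. It is overridable.
* The $\nabla g \cdot \nabla \Phi$ attraction term of geodesic active
  contours is included (toggleable); without it contours overshoot weak
  edges.
* Reinitialization keeps $\Phi$ near a signed distance. A distance transform
  of the zero-sublevel mask turned out to snap the interface back to the
  pixel grid, silently erasing sub-pixel motion between reinitializations;
  the package instead runs a few Sussman iterations
  ($\Phi_\tau = \mathrm{sign}(\Phi_0)(1 - |\nabla\Phi|)$) with the
  Russo–Smereka subcell fix anchoring interface-adjacent cells. With this
  scheme pure curvature flow tracks the analytic shrinking-circle law
  $r(t) = \sqrt{r_0^2 - 2t}$ within 2% down to $r = 10$ px, which the
  acceptance suite verifies.
* Convergence is declared when fewer than `convergence_tol` (default
  $10^{-3}$) of the enclosed pixels change between checks (every 10
  iterations), but never before `min_iters = 50`: a slowly creeping front
  can need dozens of iterations before the first pixel flips.

## Pipeline wiring

Two wiring choices differ from a naive chaining of the stages, both made
because the naive chain provably fails, and both configurable:

* **Clustering input** (`cluster_source`, default `"diffused"`). Global
  histogram equalization is a probability integral transform of the
  within-mask intensities: it maps the brain histogram to (approximately)
  uniform, which *destroys* the intensity modes k-means needs. On an
  equalized slice, 4-means returns mass quartiles — the tumor merges with
  the upper part of white matter — regardless of how well separated the
  tissues originally were. Clustering and the edge map therefore consume the
  skull-stripped, diffusion-denoised slice; the equalized slice is still
  computed and returned, serving its stated purpose of contrast enhancement
  for inspection.
* **Skull remnants and false lumps.** The stripping recipe cannot exclude a
  bright skull annulus (hole filling fills the CSF moat, merging ring and
  brain into one component), so the brightest cluster typically contains the
  skull rim along with the tumor. Cleanup of the tumor-cluster mask
  therefore drops, besides speckle (opening, `min_area` = 20 px),
  components touching the brain-mask border (`exclude_border`) — the rim
  hugs the border, genuine lumps are interior — and components that are not
  locally hyperintense (`comp_contrast_frac`, default 10% of the brain
  range over the component's 3 px surrounding ring): a slice holding fewer
  tissue classes than $K$ otherwise splits a bulk tissue and presents a
  bias-field bump as "tumor".
* **Slice emptiness.** Slices at the volume extremes contain no brain but do
  contain noise, and Otsu happily splits pure noise. A slice is flagged
  empty (never an error) when the stripped mask covers over 90% of the
  field of view or when the inside/outside mean contrast is below
  `min_contrast` (= 5) robust standard deviations of the outside; a pure
  noise split scores about 2.7 on that statistic, any slice with actual
  head tissue an order of magnitude more.

One global seed drives everything; slice $k$ derives its own stream as
`derive_seed(seed, k)`, so runs are bit-reproducible and slices independent.

## The phantom: what it emulates and what it does not

The generator renders one fixed physical head — field of view
$240 \times 240 \times 155$ mm, ellipsoidal shells for white matter, grey
matter, CSF and a bright skull annulus (semi-axes 90/95/65 mm) — sampled at
any requested grid, so a 20-slice volume is the same head at 7.75 mm slice
thickness. Tumors are star-convex lumps (smooth low-order directional
perturbation of the radius, amplitude 0.25) placed inside white matter
without mutual overlap, radius 10–25 mm by default. Intensities are tissue
means (0/40/100/150/230/210 for background/CSF/grey/white/skull/tumor on an
8-bit scale, sd 3–8) times a multiplicative low-frequency bias field
($1 \pm 0.1$), plus Gaussian noise (sd 6). The hyperintense tumor matches
the contrast-enhanced appearance the "brightest cluster" rule assumes; the
means are configurable so the "outlier" rule can be exercised too.

The phantom deliberately omits Rician noise statistics, partial-volume
mixing, k-space artifacts and multi-modal channels. Passing the phantom
acceptance therefore demonstrates that the pipeline's stages compose
correctly and recover a known truth under noise and bias — not that the
tuned defaults transfer unchanged to clinical BraTS volumes.

## Problem sizes and tolerances used by the tests

Unit tests run on a $120 \times 120 \times 9$ phantom (2 mm in-plane); the
end-to-end acceptance runs the full $240 \times 240 \times 20$ volume over
five seeds expecting Dice $\ge 0.90$ and HD95 $\le 5$ px, a two-lump volume
expecting exactly two predicted components, and bit-identical reruns. The
quantum algebra is held to $10^{-12}$; Otsu, k-means and the metric suite
are held exactly to brute-force oracles; the curvature-flow law to 2%;
mixture centroid recovery to 2% of the dynamic range in at least 9 of 10
seeds. `scripts/acceptance.R` re-runs the phantom pipeline and mixture
recovery from scratch and writes the resulting Dice, HD95, confusion rates,
component count and centroid error to JSON.

## Known limitations

* Slice-wise processing: no 3D regularization across slices; a lump visible
  in one slice only is kept if it satisfies the area and contrast rules.
* The brightest-cluster rule presumes a hyperintense tumor; hypointense
  tumors need the "outlier" strategy and a phantom configured accordingly.
* $K$ is fixed at 4; slices with fewer tissue classes rely on the cleanup
  filters described above.
* The level-set scheme is explicit and full-field; narrow-band or implicit
  schemes would be faster but are out of scope.
* Multiple lumps per slice are supported and exercised on the phantom, but
  published validations of this method family have used single-tumor
  volumes, so multi-lump behaviour should be treated as supported but less
  battle-tested.
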