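---
title: "Predicting soft-organ morphology from cranial anatomy: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting soft-organ morphology from cranial anatomy: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`tonguemorph` predicts the shape of a soft organ — the tongue — in a target
skull from a reference subject's CT anatomy. The driving idea is that the
bony structures of the head and neck carry enough information about a
subject's overall oropharyngeal geometry to morph a carefully built
finite-element (FE) tongue mesh from a reference subject onto the target,
even when no soft tissue is observable in the target (as for fossil
remains, where only bone survives). This vignette describes the models, the
parameters that matter, the synthetic phantom the package validates
against, and the numerical choices behind the implementation.

## The registration model

Let $I_h:\Omega_h\to\mathbb{R}$ and $I_b:\Omega_b\to\mathbb{R}$ be two
symmetrized, HU-valued head/neck volumes (reference and target). We seek a
transformation $T_\mu:\Omega_h\to\Omega_b$ such that $I_h(x)$ and
$I_b(T_\mu(x))$ agree, where $T_\mu$ is a free-form deformation (FFD): a
global affine map plus a displacement field written as a weighted sum of
tensor-product cubic B-spline basis functions on a regular control-point
lattice,

$$T_\mu(x) = A x + t + \sum_k B_3\!\left(\frac{x - c_k}{h}\right)\mu_k .$$

Cubic splines are the standard FFD choice: they have compact support (each
coefficient acts locally, which keeps stochastic optimization stable) and
twice-differentiable basis functions, which a well-defined bending energy
requires. The control points are axis-aligned and placed mirror-
symmetrically about the mid-sagittal plane (an odd count along the plane
axis, one column of controls on the plane), so symmetric solutions are
representable exactly; symmetry of the *coefficients* is not hard-
constrained but encouraged through the cost.

The cost has four terms,

$$F(\mu) = \mathrm{NC}(\mu; I_h, I_b) + \alpha\,\mathrm{SD}(\mu; S_h, S_b)
  + \beta\, D(\mu; L_h, L_b) + \gamma\, P(\mu),$$

* $\mathrm{NC}$ — the negative Pearson correlation between fixed and warped
  intensities over a random sample of head/neck voxels. Correlation (rather
  than SSD) makes the term invariant to affine intensity differences
  between scanners.
* $\mathrm{SD}$ — mean squared difference between the binary side-label
  images $S_h(x)$ and $S_b(T_\mu(x))$; it penalizes transforms that carry
  material across the mid-sagittal plane and so keeps symmetric inputs
  symmetric. $\alpha = 1$ by default: plane alignment is treated as exactly
  as important as intensity alignment.
* $D$ — mean Euclidean distance between 21 paired anatomical landmarks on
  bone after transformation. Landmarks are the main handle on large,
  non-homothetic global alignment; $\beta$ is scheduled per resolution
  level as $(0, 0.05, 0.1)$, coarse to fine, so the coarse level is driven
  by image content alone.
* $P$ — the bending energy, the mean over the head/neck region of the
  squared Frobenius norm of the full second-derivative tensor of $T_\mu$
  (a $3\times3\times3$ tensor; the affine part contributes nothing). It
  penalizes curvature and suppresses folding. Its weight is scheduled as
  $(0, \lambda_2/2, \lambda_2)$ coarse to fine. Weights are deliberately
  *not* normalized across terms.

The two parameters the predictions are most sensitive to are the finest
control-grid spacing $\lambda_1$ (mm) and the finest-level penalty weight
$\lambda_2$; they are exactly the axes of the uncertainty-quantification
study below.

### Optimization

The cost is minimized by adaptive stochastic gradient descent over three
resolution levels: images and control grid are both coarsened by factors 4,
2, 1 (grid spacings $4\lambda_1, 2\lambda_1, \lambda_1$), with Gaussian
pre-smoothing of $\sigma$ = half the downsampling factor (in voxels) before
subsampling. Each iteration draws a fresh random subset of head/neck-mask
voxel centers (20000 by default), evaluates all four terms and their
*analytic* gradients with respect to the coefficients (chain rule through
the B-spline weights; finite differences over $\sim 10^4$ parameters would
be infeasible and appear only as test oracles), and steps with gain
$a/(A + t)^{0.602}$, $A = 20$. The gain $a$ is auto-scaled so the first
step moves the largest coefficient by `step_delta` (default 1 mm).
Between levels the lattice is refined by the exact cubic B-spline two-scale
(subdivision) relation, so optimization continues from the coarse solution
without approximation error (verified to $10^{-10}$ mm in the tests). The
side-label term shares the sample set of the intensity term (one sampling
pass); the landmark term is evaluated on all landmarks every iteration
(cheap). With a fixed seed the entire run is bit-reproducible.

The affine component is initialized beforehand by fitting a
translation + rotation + anisotropic-scaling map minimizing the *mean*
(not squared) Euclidean distance over a small landmark subset (ids 2, 4, 7,
20, 21 by default — a non-coplanar subset that captures size change and
frontal-axis rotation), via a least-squares full-affine fit projected onto
$R\,\mathrm{diag}(s)$ and polished by direct search.

### Assessment

Two accuracy notions mirror the two study conditions. When soft tissue is
visible, accuracy is the mean distance between points annotated on the
actual organ surface and the surface of the predicted FE mesh (exact
point-to-triangle distances). When only bone is available, there is no
observable organ, so accuracy is the mean node-to-node distance between the
bone-based prediction and the soft-tissue-based prediction of the *same*
reference mesh (identical topology by construction). Mesh quality is
summarized by $J_{10\%}$: the Jacobian determinant of $T_\mu$ is evaluated
at every voxel inside the organ, and the lowest 10% (count rounded up;
the convention matters only for tiny masks) are averaged. $J = 1$ is
isochoric; values near or below zero flag collapse or folding. Candidate
predictions are ranked by

$$\mathrm{score} = \mathrm{accuracy} \times (J_{10\%} - 1)^2,$$

lowest wins; ties are broken by larger $J_{10\%}$ (prefer the better-
conditioned mesh), then smaller $\lambda_1$.

## Preprocessing

The mid-sagittal plane is defined by three user-selected points (it is an
input, not detected automatically — the points are chosen for their
efficacy in symmetrization, not anatomical meaning). The volume is rigidly
resampled so this plane coincides with the central voxel plane of the
first axis and the volume center sits at the world origin; one half is then
reflected onto the other, making the volume an exact fixed point of the
mirror operation. Which half is kept is configurable (the anatomical
left/right naming is arbitrary). For an even-sized axis the reflection
plane lies between the two central voxel layers.

The head/neck mask is a threshold slightly above air (default −900 HU)
followed by morphological closing (Euclidean ball, radius 3 voxels) and
dilation (radius 1); closing fills cavities up to its ball scale while the
intensity volume itself keeps all air–tissue interfaces — the mask only
gates where the similarity terms sample. Bone-only volumes replace every
voxel below +200 HU with −1000 HU (air); +200 HU separates soft tissue
(< 100 HU) from cortical/cancellous bone. An optional hyoid mask is also
set to air regardless of intensity, because the hyoid does not fossilize.

## Uncertainty quantification

The sensitivity of the prediction to $\lambda = (\lambda_1, \lambda_2)$ is
mapped with adaptive stochastic collocation on simplex elements. The
quantity of interest $Q(\lambda)$ (a mesh-accuracy measure; both the
surface-accuracy and node-to-node variants are provided as plug-in
evaluators) is sampled at parameter points, a piecewise-linear metamodel is
built on a Delaunay triangulation, and new samples are placed where they
most reduce the density-weighted $L^1$ interpolation error

$$\bar\eta = \int_\Lambda |Q - \Theta_h Q|\, \pi_\Lambda\, d\lambda,$$

with $\pi_\Lambda$ the parameter density: truncated Gaussian
$\mathcal{N}(20, 4)$ on $[8, 32]$ mm for $\lambda_1$, uniform on
$[0, 1000]$ for $\lambda_2$ (no prior information on the penalty weight).
The $L^1$ norm is a practical choice that tolerates discontinuous
responses. In the continuous-metric framework the optimal sampling metric
and its error have closed forms; for dimension $n = 2$ and budget $C$,

$$M(\lambda) = C\, I^{-1} \det(\pi_\Lambda |H|)^{-1/4}\, \pi_\Lambda
|H|(\lambda), \qquad
E = 2\, C^{-1} I^{2}, \qquad
I = \int_\Lambda \det(\pi_\Lambda |H|)^{1/4} d\lambda,$$

with $H$ the QoI Hessian and $|H|$ its eigenvalue-wise absolute value
(eigenvalues floored at $10^{-12}$ so the metric stays SPD at saddle and
flat points). $E \propto C^{-1}$ predicts first-order convergence in the
budget, which the test suite verifies empirically (log–log slope $-1.0 \pm
0.3$ on a quadratic QoI).

Design choices where the method leaves room:

* **Hessians from scattered samples.** $H$ is estimated per vertex by a
  weighted least-squares quadratic fit over the 10 nearest samples
  (Gaussian weights, bandwidth = median neighbour distance), computed in
  range-normalized coordinates for conditioning and mapped back to raw
  units. Exact for quadratics; rank-deficient neighbourhoods enlarge and
  then ridge-regularize.
* **Metric-conforming refinement.** The external anisotropic mesh
  generator used in the original workflow is replaced by in-package
  refinement: the edges with the greatest metric length
  $\ell_M(e) = \sqrt{e^\top \bar M e}$ are bisected (ties by lowest vertex
  index), the vertex set is re-triangulated by Delaunay, and the QoI is
  evaluated at new vertices only. This preserves what matters about the
  external tool: anisotropy, metric conformity, budget respect.
* **Delaunay in normalized coordinates.** The two parameters differ by
  orders of magnitude in units; triangulating in range-normalized
  coordinates keeps triangle quality meaningful. The empty-circumcircle
  property holds (and is tested by brute force) in those coordinates. The
  triangulation itself is an in-package Bowyer–Watson implementation,
  adequate for the hundreds of samples a collocation study uses.
* **Coverage.** The 4 domain corners are always included in the initial
  sample so the metamodel's hull equals the whole parameter domain.
* **Budget accounting.** The remaining budget is spent evenly across
  adaptation rounds (remainder to the last round); the final vertex count
  never exceeds the budget.
* **Integrals** over $\Lambda$ use centroid (midpoint) quadrature per
  triangle of the current tessellation with vertex-averaged Hessians.

## The synthetic phantom

The CT exams this class of study uses are not distributable, so validation
uses a deterministic phantom that emulates their structure: a bright bone
shell (ellipsoid, +700 HU, 6 mm thick) enclosing soft tissue (+40 HU)
containing an air cavity (−1000 HU) bounded below by a tongue-like organ
(+55 HU); 21 landmarks on the bone-shell mid-surface (19 on the midline,
2 mirrored off-midline so the affine-initialization subset is
non-coplanar); a structured tetrahedral mesh of the organ; and 608
evaluation points on the deformed organ's upper surface. HU strata are
representative clinical values. The default grid is $64^3$ at 2 mm.

The ground-truth deformation is a smooth FFD on a coarse (24 mm) lattice
with mirror-symmetrized random coefficients scaled to a maximum
displacement of 8 mm, rejected at generation if its dense Jacobian scan is
not safely positive. The moving volume is rendered by *inverting* the
ground truth (fixed-point iteration on the displacement) and evaluating
the analytic scene at $T^{-1}(y)$ — so $I_b(T(x)) = I_h(x)$ holds by
construction with no resampling blur, and the ground-truth transform
remains an explicit FFD that meshes and landmarks can be pushed through
exactly. Additive Gaussian noise (sd 10 HU) is mirrored so the moving
volume stays exactly symmetric. A coarse ground-truth lattice (≥ 20 mm) is
deliberate: the registration lattice can then represent the truth, making
recovery a well-posed question.

What the phantom does *not* emulate: anatomical shape detail (the
"skull" is an ellipsoid shell), intensity inhomogeneity and beam-hardening
artifacts, topology differences between subjects, and the large
inter-species shape differences of real cranial anatomy. Passing the
phantom study shows the machinery is correct and self-consistent — that
the optimizer recovers representable smooth deformations from bone-and-
tissue contrast — not that real cross-species predictions reach any
particular accuracy.

## Numerical choices and degenerate inputs

* Trilinear interpolation for intensities, nearest-neighbour for masks and
  labels; out-of-bounds sampling fills with −1000 HU (air) and zero
  gradient.
* Zero-variance intensity samples make the correlation undefined; the NC
  term is then defined as 0 (uninformative) and contributes no gradient.
* Landmark distances below $10^{-12}$ mm contribute zero gradient (the
  distance gradient is undefined at 0).
* If the head/neck mask has fewer voxels than `samples_per_iter`, sampling
  falls back to replacement with a warning.
* The FFD lattice always covers its domain with a two-span margin, so
  every domain point has full cubic support and one factor-2 subdivision
  stays valid on the domain; evaluation outside the support is an error,
  never an extrapolation.
* Tetrahedra are reoriented to positive volume on construction; "surface
  nodes" are the nodes referenced by stored surface triangles, or by the
  boundary faces (faces on exactly one tet) when no surface is stored.
* A cost of `NaN` aborts the run with its trace attached rather than
  continuing silently.

## Problem sizes used by the tests and the acceptance script

The phantom studies run on the $64^3$ phantom with 150 iterations and 4000
samples per level (a few seconds per registration on one core), and on a
$32^3$ phantom for unit-scale optimizer properties; the UQ convergence
study uses budgets 25–200 on analytic response surfaces. These sizes are
the package's standard miniature study conditions; the method itself has
no dependence on them, and `registration_config()` exposes the full-size
defaults (20000 samples, 2000 iterations per level).

## Known limitations

* The registration assumes symmetrized, plane-aligned, axis-aligned
  volumes; oblique orientation matrices and DICOM ingestion are out of
  scope.
* Only the FFD transformation model is provided (no diffeomorphic
  velocity-field models); invertibility is encouraged by the bending
  penalty and monitored via the Jacobian, not guaranteed.
* The parameter space for UQ is fixed at dimension 2.
* The Bowyer–Watson triangulation is $O(n^2)$ and intended for collocation-
  scale sample counts, not large point clouds.
* Mesh I/O covers Gmsh MSH 2.2, legacy VTK and ASCII STL — the formats
  needed to exchange tetrahedral organ meshes and surfaces, not general
  mesh conversion.
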