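---
title: "Phase-based diffeomorphic registration: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-based diffeomorphic registration: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphons)
```

## The registration model

The package estimates a dense displacement field $D$ on the grid of a fixed
image $f$ such that the moving image $m$ warped by the deformation
$\Delta = \mathrm{Id} + D$ matches $f$:
$f(x) \approx m(x + D(x))$. The estimation is nonparametric: three
operations — field computation $\Theta$, accumulation $\Phi$,
regularization $\Psi$ — are iterated at each level of a coarse-to-fine
image pyramid.

**Field computation.** Two updates are provided.

* The *Morphons* (phase-based) update filters $f$ and the current warped
  image $w$ with a bank of complex quadrature *loglet* filters: $K = 4$
  directions $\eta_k$ at angles $k\pi/4$ in 2D, the $K = 6$ non-antipodal
  icosahedral vertex directions in 3D. Each filter is defined in the
  frequency domain by
  $H_\eta(\omega) = \chi_+(\eta^T\omega)\,(\eta^T\hat\omega)^2 R(\|\omega\|)$
  with the log-normal radial profile
  $R(r) = \exp[-\ln^2(r/\rho)/\ln 2]$, so $R(\rho) = 1$ and
  $R(\rho/2) = R(2\rho) = 1/2$. The argument of a response is the *local
  phase*; because a positive intensity rescaling multiplies the complex
  response by a positive real number, the phase — and hence the whole
  update — is invariant to contrast changes. The per-direction dephasing
  $\Delta\phi_k = \arg(q_f\, q_w^*) \in (-\pi, \pi]$ relates to the local
  displacement through $\Delta\phi_k \approx \rho\, \eta_k^T D$, and the
  per-voxel update minimizes the certainty-weighted energy
  $\sum_k [c_k(\rho\,\eta_k^T d - \Delta\phi_k)]^2$ with
  $c_k = A_f A_w$ the product of response amplitudes. The closed-form
  minimizer $d = (N^T C^2 N)^{-1} N^T C^2 \Gamma / \rho$ is computed
  voxelwise; where the normal matrix is numerically singular (smallest
  eigenvalue below $10^{-9}$ of the largest, or all certainties below
  $10^{-12}$ of the global maximum) the update is set to zero. No phase
  unwrapping is attempted: the method relies on
  $|\rho\,\eta^T d| < \pi$ per scale, which the pyramid enforces for
  per-scale displacements below $\pi/\rho$ voxels.

* The *Demons* (intensity-based) comparator uses the classical update
  $d = (f - w)\,\nabla f / (\|\nabla f\|^2 + (f - w)^2)$, zero where the
  denominator vanishes. The sign convention is fixed by requiring descent
  of the SSD under the warp convention above; a ramp image shifted by $t$
  yields $d \approx t$. Demons carries no certainty (identically 1) and is
  accumulated undamped and regularized with a plain
  (boundary-renormalized) Gaussian.

**Accumulation.** Additive accumulation $D_a + w_u D_u$ (damping weight
$w_u = c_u/(c_a + c_u)$) is cheap but inconsistent with composing
deformations and can fold the grid. Compositive accumulation
$D_a \oplus w_u D_u$, with $D_1 \oplus D_2 = D_2 + D_1 \diamond D_2$,
makes the accumulated deformation the composition $\Delta_1 \circ
\Delta_2$. Diffeomorphic accumulation first exponentiates the damped
update, $D_a \oplus (\exp(w_u D_u) - \mathrm{Id})$, so each increment is
itself invertible. The certainty map accumulates by its self-weighted mean
$(c_a^2 + c_u^2)/(c_a + c_u)$, which never exceeds $\max(c_a, c_u)$.

**Exponential.** $\exp(D)$ is the time-1 flow of $\dot u = D(u)$,
computed by scaling and squaring: $D$ is halved $k$ times until its
maximum vector norm is below 0.5 voxels (`max_step`), the flow at
$2^{-k}$ is approximated first order, and $k$ self-compositions recover
time 1. $k = 0$ reduces to the first-order approximation. The scheme's
residual error scales like $2^{-k}\,\|\nabla D\|\,\|D\|$: it is accurate
for fields whose correlation length is large compared with their
amplitude (the regime of organ-scale motion) and degrades for velocity
gradients above roughly 0.3 per voxel. The fixed tolerances used in the
test suite (0.05 voxels against a 4096-step Euler integration of the
flow; 0.1 voxels for $\exp(-D) \oplus \exp(D)$) therefore hold in — and
only in — that regime; no finite tolerance can hold for arbitrarily sharp
"smooth" fields.

**Regularization.** Normalized convolution
$s *_h g = ((h \cdot s) * g)/(h * g)$ with a Gaussian $g$ of variance
$\sigma_\Psi^2 = 2$ voxels (truncated at $4\sigma$) smooths each field
component with the certainty as normalization, then the certainty itself.
The quotient is a weighted average, so amplitudes never grow and values
propagate from confident voxels into structureless regions. Zero padding
means certainty outside the volume is zero, removing any boundary-padding
influence. Where the denominator falls below $10^{-12}$ of its maximum
the output is set to zero.

## The multiscale driver

Images are downsampled with a boundary-renormalized Gaussian
($\sigma = \kappa^j/2$) and decimation by $\kappa^j$ ($\kappa = 2$).
At each scale, from coarse to fine, the loop warps, updates, accumulates
and regularizes until the relative SSD change drops below $10^{-4}$
(0.01%) — after at least 10 and at most 20 iterations — then upsamples
the field (linear interpolation, vector values multiplied by $\kappa$).
The same filter bank is applied at every scale; filtering the downsampled
images realizes the doubling of the probed frequency per level.

Two choices here were genuinely open and deserve their rationale:

* **Depth of the pyramid.** The coarsest grid is required to keep at
  least `kernel_size` (9) voxels per axis. A stricter factor-two margin
  was considered and rejected: the truncated kernels' effective width is
  only $\approx 1/\rho$ voxels, and the deep blob-scale levels are what
  give the pyramid its large-displacement capture range. On the
  missing-structure phantom (below) the deepest level is essential for
  the central collapse to be found at all.

* **Certainty across scales.** The certainty map restarts from zero at
  every scale rather than being upsampled with the field. Certainties of
  differently downsampled images are not commensurate, and the first
  accumulation at a fresh scale should be undamped
  ($c_u/(0 + c_u) = 1$). Empirically, carrying stale certainty across
  scales anchors the field in smooth local optima and prevents the
  collapse of unmatched structures that the method is expected to
  produce.

## Tunable parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `rho` | $\pi/2$ | rad/voxel | filter center frequency (wavelength 4 voxels); also caps the per-scale displacement at $\pi/\rho = 2$ voxels |
| `kernel_size` | 9 | voxels | spatial extent of the truncated quadrature kernels |
| `sigma_psi_sq` | 2 | voxels$^2$ | variance of the regularization Gaussian |
| `scales` | 8 | – | requested coarsest pyramid level, capped by the grid size |
| `kappa` | 2 | – | subsampling factor between levels |
| `min_iters`, `max_iters` | 10, 20 | – | per-scale iteration bounds |
| `ssd_rel_tol` | $10^{-4}$ | – | relative SSD stagnation threshold |
| `max_step` | 0.5 | voxels | scaling threshold of the field exponential |

Fields are stored and composed in voxel units of the current fixed grid;
physical spacing enters only when reporting landmark errors in mm. With
anisotropic spacing the arithmetic is unchanged — a documented
limitation, since the regularization kernel is then anisotropic in
physical space.

## What the phantoms emulate

`phantom_scaled_disks()` reproduces the contrast-change experiment: two
identical blurred disks (128$^2$, radius 30, blur $\sigma = 2$), the
moving one multiplied by 0.75. The phase-based update is exactly zero on
this pair; the intensity-based update is not, and full Demons
registration deforms the rim by several voxels.

`phantom_hole_disks()` reproduces the missing-structure experiment: the
fixed image is a disk of radius $r_1 + r_2 = 40$ with a bright central
spot of radius $r_2 = 10$; the moving image is a plain disk of radius
$r_1 = 30$ at the annulus intensity. The bright-spot reading of the
central structure was chosen over a dark hole; the collapse dynamics are
similar for both. Since the moving image has no counterpart for the
spot, a good registration maps the central region to (almost) a single
point: the Jacobian determinant approaches zero there. With this
implementation the diffeomorphic run ends with a minimum Jacobian of
about $+0.08$ — compressed a thousand-fold in area but not folded —
while over-iterating past the SSD-stagnation stop drives *both*
accumulation modes slightly negative, because the regularization applied
after accumulation is not invertibility-preserving at a near-singular
point. The strong, persistent folding of the additive mode that
motivates diffeomorphic accumulation on clinical data is therefore only
marginally visible on this phantom; the additive/diffeomorphic contrast
here is one of degree, not the clean sign separation seen on real
images, and the corresponding check in the test suite documents this
honestly rather than papering over it.

`random_diffeo()` and `phantom_textured()` supply ground truth for
recovery tests. Velocities are Gaussian-smoothed white noise, *tapered to
zero over a $2\times$`smoothness` margin at the boundary* — a
diffeomorphism of a bounded grid must map the grid into itself; without
the taper, no implementation with clamped resampling can satisfy
$\exp(-D) \circ \exp(D) = \mathrm{Id}$ near the faces. The textured pair
deforms a band-limited texture (noise smoothed with $\sigma = 1.5$
voxels, a CT-like point spread) by $\exp(V)$ with amplitude 4 voxels and
smoothness 24 at 256$^2$ — organ-scale motion inside the validity regime
of the exponential, so that the generator's own truth field
$\exp(-V)$ (the exact inverse, which a registration of the pair should
recover) carries negligible scheme error. Sharper textures are
deliberately avoided: with a $\sigma = 1$ texture the double resampling
(one to build the pair, one to evaluate the registration) already costs
5.5% of the initial SSD *with the exact field*, which would say nothing
about registration quality.

What passing these tests does **not** show: robustness to noise and
imaging artifacts, to intensity relationships beyond positive local
scaling, to sliding motion (discontinuous fields), or to anisotropic
clinical volumes — none of which the generators emulate.

## Numerical choices

* Warping uses linear interpolation with out-of-grid coordinates clamped
  to the boundary; label masks use nearest-neighbour. Image convolutions
  (filters, Gaussians) use zero padding; pyramid antialiasing and the
  Demons regularization renormalize at the boundary so constants are
  preserved.
* Jacobians use centered differences in the interior and one-sided
  differences at boundary voxels (exact on affine deformations).
* The per-voxel $3\times3$ normal-matrix inverse uses the closed-form
  adjugate with a trigonometric symmetric-eigenvalue singularity test.
* Kernel synthesis samples $H_\eta$ on a 64-per-axis (2D) or 32-per-axis
  (3D) DFT grid, inverse transforms, centers, truncates, and removes the
  residual DC component of the real part.
* Ties and degenerate inputs: zero-certainty voxels get zero updates;
  a zero denominator in any guarded quotient yields zero; `exp_field`
  of the zero field returns it unchanged.

## Problem sizes in the shipped tests

The test-suite experiments run at the sizes stated above (128$^2$
disks, 256$^2$ textured recovery, 96$^2$ exponential-versus-Euler
comparisons with a 4096-step integrator on a stride-2 point set, 1000
solver-versus-grid-search instances, 16$^3$ metric oracles), chosen so a
single desk-class core reproduces every number in minutes.
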