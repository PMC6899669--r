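---
title: "Differentiable CT reconstruction with difftomo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differentiable CT reconstruction with difftomo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(difftomo)
```

## The model

X-ray CT measures line integrals of an attenuation map.  Discretized, the
acquisition is the linear system

$$ A x = p, $$

where $x$ is the volume on a regular grid, $p$ the stack of detector
measurements over all views, and $A$ the *system matrix* — far too large to
store, so `difftomo` applies it on the fly: the **ray-driven forward
projector** casts one ray per (view, detector pixel), marches it from
volume entry to exit, and accumulates bilinearly (trilinearly) interpolated
samples times the step length, yielding a true line integral in value·mm.

Filtered backprojection realizes the pseudoinverse factorization

$$ \hat{x} = A^{\top} F^{H} K F \, p, $$

a row-wise Fourier filter with diagonal ramp weights $K$ followed by a
backprojection.  The **voxel-driven back projector** implements the
$A^\top$-like smearing: each voxel looks up and interpolates its detector
coordinate in every view and accumulates, scaled by the angular increment
$\Delta\beta$, plus the FDK distance weight $U^{-2}$ for divergent beams
when requested.

Because the ray-driven forward projector and the voxel-driven back
projector discretize differently, they are an **unmatched pair**: the
voxel-driven operator is not the transpose of the discretized forward map.
The package quantifies this directly — `explicit_system_matrix()`
materializes $A$ column by column for tiny problems, and the dot-product
test $\langle Ax, y\rangle = \langle x, A^\top y\rangle$ separates the
three operators (forward, exact transpose, voxel-driven smearing).

## Differentiable layers and the registered gradient

Every operator is exposed as a `differentiable_op`: a forward map paired
with a *registered gradient* that maps an upstream gradient back to the
input space, so chains of projectors, filters and reconstructions are
differentiable end to end and can serve as fixed, known layers inside
trainable pipelines.

A design decision worth spelling out: the registered gradient of
`projector_layer()` is the **exact transpose** of the ray-driven forward
kernel (`forward_project_transpose()`, the same ray march scattering
instead of gathering), not the voxel-driven back projector.  Likewise
`backprojector_layer()` registers the exact transpose of the voxel-driven
kernel.  The alternative — registering the unmatched counterpart, which is
common because it reuses the reconstruction kernels — makes the layer's
"gradient" wrong by exactly the unmatched discrepancy (of order a percent
on desk-scale problems, see the test suite), which is orders of magnitude
above any sensible finite-difference tolerance and breaks the descent
guarantees of the iterative solvers below.  With exact transposes, the
central-difference check `finite_difference_gradcheck()` holds to
$\sim 10^{-10}$ in double precision, and objective monotonicity in the
iterative solver is a theorem rather than a hope.  The unmatched pair
remains first-class — `back_project()` *is* the FBP backprojector — and its
dot-product discrepancy is reported by the acceptance script.

## Geometry conventions

All of these are bit-exact contracts used by the tests:

* World coordinates in mm, isocenter at the origin, right-handed, circular
  orbit in the $z = 0$ plane.
* View angle $\beta$: central ray direction $(-\sin\beta, \cos\beta)$,
  detector axis $u = (\cos\beta, \sin\beta)$; at $\beta = 0$ rays travel
  along $+y$.  Angles are uniform on the half-open interval
  $[\text{start}, \text{start} + \text{range})$.
* The fan/cone source sits at $-\mathrm{SID}\cdot(-\sin\beta, \cos\beta)$;
  the detector center at $\mathrm{SDD} - \mathrm{SID}$ beyond the
  isocenter.
* Detector pixel $i$ (0-based) is a pixel *center* at coordinate
  $s = (i - (n-1)/2)\,\tau + \text{offset}$.
* Voxel $i$ (0-based) has its center at `origin + i * spacing`; the default
  origin centers the grid on the isocenter.  Interpolation at exact grid
  points returns the grid value; samples and detector lookups outside any
  grid contribute zero (zero-padding semantics).
* Cone-beam views are $3\times4$ projection matrices
  $P = K\,[R\,|\,t]$ with the principal point at the detector center and
  homogeneous depth $w$ equal to the distance from the source along the
  principal ray (mm).  Rays are derived from the matrix (camera center and
  $M^{-1}(u, v, 1)^\top$), so calibrated matrices from real systems drop
  in; the FDK weight assumes the stated $w$ normalization.

## Filtering, weights and normalization

`ramp_frequency_filter()` samples $|\omega|$ in cycles/mm on the padded DFT
grid (DC weight 0, Nyquist weight $1/2\tau$).  With the $\Delta\beta$
factor applied inside `back_project()`, a parallel scan covering $[0,\pi)$
reconstructs absolute attenuation values with no further constant — this
scaling was derived from the continuous FBP identity and is pinned down by
the self-consistency tests (reconstruction RMSE a few percent of the
phantom's dynamic range, which would fail at the ~50% level if any factor
of $\pi/2$ were misplaced).  `ramlak_kernel()` is the classical
band-limited spatial counterpart ($h(0) = 1/4\tau^2$, odd taps
$-1/k^2\pi^2\tau^2$); its padded DFT matches the ramp to well under 1%
away from DC.  Rows are zero-padded to the next power of two at least
twice the row length to suppress circular-convolution wrap.

Divergent beams add two weight maps before filtering: the **cosine**
obliquity weight ($\cos\gamma$ for fan, $\mathrm{SDD}/\sqrt{\mathrm{SDD}^2
+ u^2 + v^2}$ for cone) and, for short scans over $\pi + 2\gamma_m$, the
**Parker** $\sin^2$ redundancy weights.  In this package's frame the ray
$(\beta, \gamma)$ is re-measured at $(\beta + \pi - 2\gamma, -\gamma)$, and
the wedge formulas are oriented so that every conjugate pair sums to one
(verified to $10^{-12}$ on a dense grid); the sign convention of $\gamma$
is not universal across the literature, so the redundancy identity — not a
formula transcription — is the contract.  Fan and FDK reconstructions
filter at the detector spacing rescaled to the isocenter plane
($\tau\,\mathrm{SID}/\mathrm{SDD}$) and back-project with the $U^{-2}$
distance weight.  FDK accepts a full $2\pi$ orbit as well (uniform
redundancy, sum halved).

## Iterative reconstruction and filter learning

`iterative_tv()` minimizes

$$ f(x) = \lVert Ax - p \rVert_2^2 + \lambda\, TV_\varepsilon(x) $$

by gradient descent, treating the volume as the only trainable quantity
behind a fixed projector layer: $\nabla f = 2A^\top(Ax - p) +
\lambda \nabla TV_\varepsilon$.  $TV_\varepsilon$ is the isotropic total
variation with an $\varepsilon$-smoothed magnitude (forward differences,
replicated far boundary), chosen over subgradient formulations because it
is reproducible and finite-difference-checkable; its analytic gradient is
the negative divergence of the normalized differences.  Steps use halving
backtracking whenever the objective would increase, so the returned trace
is non-increasing by construction; after an accepted step the step grows
back toward the configured maximum.  The solver is deliberately a plain
first-order loop — the "training" view of iterative reconstruction — not
FISTA/ADMM.

Defaults and units: `lambda_tv` multiplies a TV measured in value·voxel
units against a data term in (value·mm)²; `tv_epsilon` is in the units of
the voxel values (use ~$10^{-3}$ of the value scale for natural-image-like
phantoms; the $10^{-6}$ default is effectively unsmoothed).  The
sparse-view demonstration in the acceptance script uses a 30-view scan of
the 128² Shepp-Logan phantom with $\lambda = 2$, $\varepsilon = 10^{-3}$,
100 iterations, step $2\times10^{-4}$, FBP warm start — settings chosen
once as a representative sparse-CT configuration.

`learn_fbp_filter()` treats the diagonal Fourier weights $K$ (half
spectrum over non-negative frequencies, symmetric extension implied) of
the FBP pipeline $\hat x = B F^{-1} K F p$ as free parameters and fits
them to (sinogram, reference) pairs by first-order descent through the
differentiable chain.  The problem is a convex quadratic, but badly
conditioned: the descent rate of weight $k$ scales with the sinogram's
spectral energy at $k$, which decays steeply, so plain gradient descent
stalls at high frequencies.  The default therefore scales the descent
direction by a per-frequency Jacobi preconditioner (squared column norms
of the linear pipeline, computed once) and takes exact line-search steps —
still first-order descent on the same objective, monotone by construction,
but convergent in tens of iterations.  On many-view noiseless data the
learned spectrum matches the analytic ramp (cosine similarity > 0.96 in
the acceptance run), with the expected noise in the weakly-determined
high-frequency tail; on an 8×8 problem small enough to materialize, the
learned filter's loss lands within ~5% of the normal-equations optimum.

## Phantoms and the analytic oracle

Phantoms are additive sets of primitives (rotated ellipses/ellipsoids and
axis-aligned boxes) rasterized by sub-voxel supersampling, including the
canonical 10-ellipse Shepp-Logan head phantom in both the original
("standard") and the high-contrast ("modified") grey-level variants,
scaled to the volume's physical extent.  The ellipsoid $z$-parameters of
the 3D extension are a documented convention (the table popularized by the
`phantom3d` implementation), not part of the original publication.

`analytic_sinogram()` is the validation oracle: the closed-form Radon
transform of an ellipse is a scaled chord length
$2ab/W^2\,\sqrt{W^2 - t^2}$, exact to machine precision, mass-conserving
($\int p\,\mathrm{d}s = \text{area}\times\text{value}$ per view).

**What agreement with the oracle does and does not show.**  The projector
is compared against the *exact* transform of a *voxelized* phantom.  At
rays nearly tangent to a primitive's edge the two must disagree: the voxel
grid spreads the edge over ~one voxel while the true chord varies like a
square root there, giving a pointwise discrepancy of order
$\tfrac12\sqrt{2\,\Delta/R}$ of the sinogram peak ($\Delta$ voxel size,
$R$ the edge's curvature radius) — several percent at desk scale, for any
sampled representation, independent of supersampling or march step.  The
tests therefore check the max error *away from the tangent band* (<1%),
the global RMS (≈0.2% of peak), rotation invariance of a centered disk
away from its tangent band, and first-order convergence of the march in
the step size against a near-continuum march; the representation floor
itself is reported, not hidden.  Synthetic phantoms also have none of the
noise, scatter, beam hardening or calibration error of real projections,
so passing tests certify the operators and pipelines, not detector
physics.

## Numerical choices

* Fixed-step ray marching (default step: half the smallest voxel spacing)
  with bi/trilinear sampling, the CPU analogue of a GPU kernel-interpolated
  projector; exact Siddon/Joseph traversal was rejected to keep the
  sampled-line-integral character, with the materialized-matrix oracle
  bounding the consequences.
* All reconstruction normalization constants live in `fbp()`; the
  projector pair stays a clean adjoint pair for gradients (documented
  contract: `back_project()` is $\Delta\beta$-scaled, its transpose
  matches).
* Double precision everywhere in memory (gradient checks demand it);
  float32 on disk by default for MHD volumes.
* Degenerate inputs: empty primitive lists rasterize to zero volumes; rays
  missing the volume and voxels projecting off the detector contribute
  exact zeros; projection through a point at or behind the source raises a
  degenerate-projection error; Parker weights refuse ranges that are not a
  short scan within $10^{-6}$.
* Problem sizes in the tests and acceptance script (256² / 360 views in
  2D, 64³ / 180 views in 3D, 16² for materialized-matrix and gradient
  oracles) were chosen as the smallest sizes at which the studied effects
  are comfortably resolved.

## Known limitations

* Circular trajectories only; no helical or arbitrary orbits, no detector
  tilt/skew intrinsics.
* One CPU interpolation path (no GPU texture path, no shear-warp
  projectors); no matched Joseph/Siddon pair as the default operator.
* FDK is the usual approximation away from the orbit plane; the tests pin
  it down only on the central slice.
* The filter-learning demo fixes its own experimental settings (views,
  noiseless data, optimizer); it demonstrates the mechanism, not a tuned
  learned reconstructor.

## A worked example

```{r example, eval = FALSE}
vg <- volume_geometry(c(256, 256))              # 1 mm voxels
g  <- scan_geometry("parallel2d", vg, detector_geometry(367), n_views = 360)
ph <- shepp_logan(vg)
sino <- forward_project(ph, g)
rec  <- fbp(sino)
sqrt(mean((rec$values - ph$values)^2)) / diff(range(ph$values))
#> ~0.027  (relative RMSE against the phantom)
```

The acceptance script (`scripts/acceptance.R`) re-runs this and every
other headline computation from scratch; see the README for how to invoke
it.
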