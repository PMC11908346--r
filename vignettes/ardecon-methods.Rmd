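---
title: "Restoring anisotropic-resolution cryo-EM maps: model, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Restoring anisotropic-resolution cryo-EM maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A single-particle cryo-EM reconstruction is assembled from projections of
many particle copies. Each projection contributes a central slice to the
3D Fourier transform, so the orientation distribution of the particles is
also the sampling distribution of Fourier space. When particles prefer
certain orientations, parts of Fourier space are under-sampled — in the
limiting case (all projection directions more than some angle away from an
axis) a **double cone** around that axis is empty. In real space the
reconstruction is then the ideal map convolved with an anisotropic point
spread function: density elongates along the cone axis, separations between
strands blur, and directional resolution estimates diverge even when the
global FSC still looks respectable.

`ardecon` implements a three-stage restoration: measure the anisotropy
(directional FSC), encode it as a transfer function (OTF), and invert it
(entropy-regularized deconvolution).

## Directional FSC

The standard Fourier shell correlation between half-maps,
$\mathrm{FSC}(s) = \mathrm{Re}\sum F_1 F_2^* / \sqrt{\sum|F_1|^2\sum|F_2|^2}$,
averages over whole spherical shells. The directional variant computes the
same ratio over **conical shells**: for a direction $\hat d$ (one of 500
from a deterministic Fibonacci lattice) the sum runs over shell voxels
whose frequency vector — or its Friedel mate — lies within 20° of
$\hat d$ (apex angle 40°, read as the full cone opening; including the
Friedel mate makes every quantity exactly centro-symmetric).

Two kinds of degenerate shell are distinguished, and the distinction
matters downstream:

* **unsampled** shells contain no voxels at all (the innermost shells of a
  narrow cone on a small grid). Nothing is knowable there; they are
  *skipped* when rendering and when estimating resolutions.
* **zero-power** shells contain voxels but no signal in at least one input
  (the situation inside a missing cone). That is a *measured* zero
  correlation; it is kept as the value 0.

Collapsing the two (either counting unsampled shells as zero, or skipping
zero-power shells) produces artifacts: the first drags the dFSC of
identical half-maps below 1 at low radii; the second lets the rendering's
nearest-direction fallback paint rim values into a genuinely empty cone.

The 500 curves are rendered as a 3D volume: each Fourier voxel takes the
average of the curves of all directions whose cones contain it, weighted
by the cosine of the angular distance to each cone axis, clamped to
$[0,1]$. The DC voxel — where no direction is defined — takes the
directional mean of the first shell. Voxels covered by no cone (possible
only for very sparse direction sets) fall back to the angularly nearest
direction with a measured value.

**Resolution estimation** reports the reciprocal of the first downward
crossing of the threshold (0.143 for half-map curves, 0.5 against a
reference), linearly interpolated between shell centers; a curve that
never crosses reports Nyquist ($2\,\mathrm{ps}$), a curve starting below
the threshold reports the coarsest shell with a warning.

## OTF construction

The damping factor is built analytically in Fourier space as
$\exp(-2\pi^2\sigma^2 |k|^2)$ ($|k|$ in cycles/voxel) with
$\sigma = \mathrm{res}/(\pi\sqrt2\,\mathrm{ps})$ voxels, the unique width
for which the value at frequency $1/\mathrm{res}$ is exactly $1/e$ of the
DC value (the molmap convention). `res` defaults to the global half-map
FSC = 0.143 resolution. Constructing the Gaussian analytically avoids
real-space discretization error at small $\sigma$. Note that $\sigma$
*grows* with `res`: coarse resolutions mean strong damping, and the
undamped limit is `res` → 0, not `res` → ∞.

The OTF is the voxelwise product of the rendered dFSC volume and this
Gaussian, normalized to 1 at DC, clamped to $[0,1]$, and zeroed beyond
Nyquist.

## Entropy-regularized deconvolution

The restored map minimizes

$$J(g) \;=\; \frac{1}{N^3}\bigl\lVert \mathrm{OTF}\cdot\mathcal F g - \mathcal F m\bigr\rVert^2
\;+\; \lambda \sum_r w(r)\,\lVert H g(r)\rVert_F^2,
\qquad w(r) = \frac{1}{1 + g(r)^2/\delta^2},$$

with $H$ the second-finite-difference Hessian under periodic boundaries
(all six distinct entries, cross terms counted twice) and $m$ the observed
full map. The data term equals the real-space sum of squared residuals
(Parseval). The weight $w$ makes the roughness penalty *signal-adaptive*:
where the map is strong relative to the nonlinearity scale $\delta$,
smoothing relaxes and sharp features survive; large $\delta$ approaches
uniform (quadratic) smoothing.

**Scale convention.** The adaptive weight only departs from 1 when map
values approach $\delta$. The published defaults ($\delta = 10^4$, grid
$1\ldots10^7$) stem from classic widefield deconvolution, whose inputs are
photon-count intensities in the thousands. The solver therefore rescales
the observed map to a fixed internal peak amplitude of $10^4$ and scales
the result back. This makes the default parameters meaningful for maps of
any scale and the solver equivariant under input rescaling. It is also
essential for missing-cone recovery: with $w \equiv 1$ the regularizer is
a circulant quadratic form, diagonal in Fourier space, and provably cannot
move amplitude into unmeasured frequencies — the *nonlinearity is the
inpainting mechanism*.

**Optimizer.** Nonlinear conjugate gradient (Polak–Ribière⁺, automatic
restarts) with an Armijo backtracking line search; initialization is the
observed map, no randomness anywhere, objective non-increasing by
construction. Convergence is declared after three consecutive relative
objective changes below `tol` (default 1e-5), capped at `max_iters`
(default 100). Fourier voxels with OTF < 1e-6 are excluded from the data
term entirely, so the missing cone is driven only by the regularizer —
no division-style amplification can occur. Positivity projection is
available but off by default (refined cryo-EM maps are signed and roughly
zero-mean). `deconvolve()` returns the raw solver output; the pipeline
normalizes (mean 0, sd 1) at the very end, controllable by a flag.

Tunable parameters, with units and defaults:

| parameter | meaning | default |
|---|---|---|
| `smoothing` ($\lambda$) | weight of the roughness penalty (dimensionless, both terms extensive) | 0.5 |
| `nonlinearity` ($\delta$) | map amplitude (internal scale) where smoothing starts to relax | 1e4 |
| `max_iters`, `tol` | iteration cap / relative-change stop | 100, 1e-5 |
| `n_dirs`, `apex_angle` | dFSC sampling | 500, 40° |
| `fsc_threshold` | half-map resolution threshold for the Gaussian | 0.143 |
| mask `edge_width` | soft-edge width of the bounding-sphere mask | 20 voxels |
| reference low-pass | resolution for `prepare_reference` | 6 Å |

`grid_search()` screens $(\lambda, \delta)$ pairs against a reference map,
scoring each deconvolution by the mean directional-FSC value (a scalar
area-under-curve surrogate for the side-by-side curve comparison the
screening procedure is based on); the default grids are the published
18 × 8 values.

## What the synthetic generator emulates — and what it does not

`degrade()` models preferred orientation **at the volume level**: the
half-maps are $\mathcal F^{-1}[\mathcal F(\text{truth} + \text{noise}_i)\cdot W]$
with a shared coverage weight $W$ and independent white Gaussian noise
fields (noise sigma expressed relative to the truth RMS; default 0.5).
Noise passes through the coverage weighting because an experimental
reconstruction has no content of any kind — signal or noise — at
unsampled frequencies; its transform shows a genuinely empty cone. The
coverage can be an analytic cone complement or the slab-accumulated
`sampling_weight_volume` of an orientation table (central-slice model,
slab half-width 1 voxel); the 60°/120° tilt-band filter on a uniform
orientation table retains exactly half the particles and reproduces the
classic 30° missing double cone.

This is exactly the ideal-map ⊛ PSF model that motivates deconvolution,
so a green recovery test establishes that the pipeline inverts *that*
model. It does **not** establish performance on effects the generator
omits: per-particle CTF, B-factor envelopes, alignment errors, structured
(non-white) noise, partial rather than empty cones, or reconstruction-
algorithm regularization. The blob phantom (anisotropic Gaussians of 1–3
voxel width at 1 Å/voxel, amplitudes 0.5–1.5, centers in the central 70%
sphere) mimics secondary-structure-scale feature sizes, not real protein
topology.

A subtlety worth recording: the blob phantom is *genuinely* anisotropic
(axis-aligned anisotropic blobs), so isotropy properties are tested with a
band-limited white-noise truth instead (low-passed to 3.2 Å), whose sharp
spectral edge also pins the threshold crossing tightly. With 40° cones on
a 64³ grid a conical shell near the crossing holds only a few hundred
voxels, so per-direction resolution estimates carry percent-level sampling
noise; properties about direction-to-direction spread are only meaningful
in that well-conditioned world (measured spread 2.7–6.2% over five seeds,
versus an irreducible 30%+ for the blob phantom).

## Numerical choices

* FFTs are base R's, unnormalized forward; Parseval therefore reads
  $\sum|g|^2 = \sum|\hat g|^2/N^3$. All Fourier volumes are DC-centered
  (voxel $\lfloor N/2\rfloor + 1$).
* Shells are 1 Fourier voxel wide, centers at integer radii, reported to
  Nyquist inclusive; FSC values are clamped to $[-1, 1]$.
* The low-pass filter's raised-cosine transition band (2 Fourier voxels
  wide) *ends* at $1/\text{resolution}$, so the stop band is exactly zero.
  The cost is a slightly early pass-band edge on very small grids.
* The bounding-sphere mask centers on the suprathreshold bounding box and
  covers every suprathreshold voxel, with a raised-cosine falloff over
  `edge_width` voxels; values in $[0,1]$, monotone along rays.
* Cone membership tests use $|\hat k \cdot \hat d| \ge \cos(\text{half-angle})
  - 10^{-12}$; the missing-cone mask uses a strict inequality so the mask
  vanishes as the half-angle goes to 0, and its DC voxel is 0 (so the
  complementary coverage preserves the mean).
* Line-search failure along the steepest descent direction (gradient at
  round-off) terminates the solver with the trace intact; NaN inputs are
  rejected up front.
* All generators draw from a locally seeded RNG and restore the caller's
  RNG state; reruns are byte-identical.

## Known limitations

* The deconvolution functional is a faithful-contract reimplementation of
  entropy-regularized deconvolution, not a numerical clone of any existing
  binary; only qualitative and phantom-recovery behavior is asserted.
* Recovery inside the cone is partial by construction: the regularizer
  supplies smoothness, not the missing experimental information. In the
  bundled 64³ experiment the in-cone map-to-truth resolution recovers to
  within ~0.4 Å of the out-of-cone value but not beyond it.
* With 40° rendering cones, dFSC/OTF values inside a 30° missing cone are
  boundary-smoothed (rendering cones overlap the cone edge); statements
  about "inside" values are only clean at matched radii or for strictly
  interior direction partitions.
* No CTF handling, no non-cubic grids, no map symmetrization, no GPU.
* 3D refinement itself is out of scope: `prepare_reference()` exports a
  low-passed, normalized map for an external refinement package; the
  iterative refine–deconvolve loop is documented, not executed.
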