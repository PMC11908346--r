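# ardecon

Restoration of single-particle cryo-EM density maps with **anisotropic
resolution** caused by preferred particle orientation.

When particles adopt preferred orientations in vitreous ice, some projection
directions are missing. By the central-slice theorem the corresponding
Fourier regions of the 3D reconstruction are never sampled — in the extreme
case a **missing double cone** — and the map is effectively the ideal
structure convolved with an anisotropic point spread function (PSF): density
smears along the under-sampled axis, helical pitches blur, side chains
vanish. `ardecon` measures this anisotropy and partially reverses it by
deconvolution. The package is aimed at cryo-EM practitioners who have a 3D
refinement (two half-maps plus a full map) and want an isotropized map for
interpretation or as a reference for further angular refinement.

## Method

1. **Directional FSC (dFSC).** For each of 500 directions sampled with a
   Fibonacci spherical lattice, the Fourier shell correlation between the
   two half-maps is computed over the voxels of a cone (apex angle 40°)
   about that direction:

   `dFSC_d(s) = Re Σ F₁ F₂* / sqrt(Σ|F₁|² Σ|F₂|²)`,

   the sums running over the voxels of conical shell `s`. The 500 curves
   are rendered into a 3D Fourier volume by cosine-weighted averaging over
   the cones covering each voxel.

2. **OTF construction.** The rendered dFSC volume is multiplied by the
   Fourier transform of a spherical Gaussian whose width
   `σ = res / (π √2 · ps)` (in voxels) puts the 1/e attenuation point at
   frequency `1/res`, where `res` is the global half-map resolution at
   FSC = 0.143 and `ps` the pixel size in Å. The product, normalized to 1
   at DC, is the optical transfer function (OTF).

3. **Entropy-regularized deconvolution.** The restored map `g` minimizes

   `J(g) = N⁻³ ‖OTF·F g − F m‖² + λ Σ_r w(r) ‖H g(r)‖²_F`,
   `w(r) = 1 / (1 + g(r)²/δ²)`,

   where `m` is the observed full map, `H` the second-finite-difference
   Hessian and `w` a signal-adaptive weight that relaxes smoothing where
   density is strong. Defaults: smoothing `λ = 0.5`, nonlinearity
   `δ = 1e4`. Fourier voxels where the OTF vanishes (the missing cone)
   receive no data-term gradient, so they are inpainted purely by the
   regularizer. The minimizer is a deterministic nonlinear conjugate
   gradient with a backtracking line search (objective guaranteed
   non-increasing).

A synthetic-data module (`make_phantom`, `missing_cone_mask`, `degrade`,
orientation tables with the 60°/120° tilt-band filter) generates fully
controlled missing-cone datasets so the entire pipeline is testable without
any experimental download.

## Worked example

Simulate a 64³ phantom reconstruction with a 30° missing cone and 50%
relative half-map noise, then restore it:

```r
library(ardecon)

truth <- make_phantom(64, pixel_size = 1, n_blobs = 30, seed = 0)
cone  <- missing_cone_mask(64, half_angle = 30)
ds    <- degrade(truth, voxel_grid(1 - cone$data, 1), noise_sigma = 0.5, seed = 0)

res <- run_ardecon(ds$half1, ds$half2, ds$full)   # defaults: 500 dirs, 40 deg,
print(res$decon)                                  # lambda 0.5, delta 1e4
cat(sprintf("half-map resolution (FSC 0.143): %.2f A\n", res$resolution))

stats_of <- function(m) {
  dd <- compute_dfsc(normalize_map(m), normalize_map(truth), n_dirs = 500)
  cone_partition_stats(dd, c(0, 0, 1), 30, threshold = 0.5)
}
before <- stats_of(ds$full); after <- stats_of(res$decon$map)
cat(sprintf("map-to-truth resolution inside / outside the 30-degree cone:\n"))
cat(sprintf("  before deconvolution: %5.2f A / %.2f A\n",
            before$resolution_inside, before$resolution_outside))
cat(sprintf("  after  deconvolution: %5.2f A / %.2f A\n",
            after$resolution_inside, after$resolution_outside))
```

Output:

```
<decon_result> 24 iterations, objective 1.02806e+11 -> 1.38709e+10, converged
half-map resolution (FSC 0.143): 3.59 A
map-to-truth resolution inside / outside the 30-degree cone:
  before deconvolution: 64.00 A / 3.74 A
  after  deconvolution:  3.77 A / 3.35 A
```

Reading: before deconvolution the missing cone carries no information at
all (the in-cone map-to-truth dFSC never reaches 0.5, so the estimate
falls back to the coarsest shell, 64 Å). After deconvolution the in-cone
resolution is restored to 3.77 Å — nearly matching the 3.35 Å outside the
cone — i.e. the inside/outside anisotropy collapses from ~60 Å to ~0.4 Å.

## Command line

Every stage is a subcommand of the installed `exec/ardecon` script (or
`ardecon_main()` in R):

```sh
ardecon simulate --shape 64 --cone 30 --noise 0.5 --seed 0 -o sim/
ardecon run --half1 sim/half1.mrc --half2 sim/half2.mrc --map sim/full.mrc -o decon.mrc
ardecon dfsc --half1 sim/half1.mrc --half2 sim/half2.mrc -o report
ardecon tune --map sim/full.mrc --half1 sim/half1.mrc --half2 sim/half2.mrc \
             --reference sim/truth.mrc -o scores.csv
ardecon mask --map sim/full.mrc --level 0.02 --edge 20 -o mask.mrc
ardecon reference --map decon.mrc --resolution 6 -o ref.mrc
```

`run` writes the deconvolved map plus the dFSC volume, the OTF, the
per-direction curves (CSV) and a JSON parameter log.

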