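# Optical transfer function construction.
#
# The OTF used for deconvolution is the product of (a) the rendered 3D dFSC
# volume, which encodes direction-dependent information transfer of the
# reconstruction, and (b) the Fourier transform of a spherical real-space
# Gaussian, which acts as an overall B-factor-like damping suppressing
# high-frequency noise build-up.

#' Real-space width of the damping Gaussian
#'
#' `sigma = res / (pi * sqrt(2) * ps)` in voxels, the unique width for which
#' the Fourier transform of `exp(-x^2 / (2 sigma^2))` falls to 1/e of its
#' maximum at spatial frequency `1/res` (the convention of UCSF Chimera's
#' molmap).
#'
#' @param res resolution in Angstrom (positive).
#' @param ps pixel size in Angstrom (positive).
#' @return sigma in voxels.
#' @export
gaussian_sigma <- function(res, ps) {
  if (res <= 0 || ps <= 0)
    stop("gaussian_sigma: res and ps must be positive")
  res / (pi * sqrt(2) * ps)
}

#' Fourier transform of the spherical damping Gaussian
#'
#' Constructed analytically in Fourier space as
#' `exp(-2 pi^2 sigma^2 |k|^2)` with `|k|` in cycles/voxel, so the value at
#' DC is exactly 1 and the value at frequency `1/res` (1/A) is exactly 1/e.
#'
#' @param shape grid size N (>= 8).
#' @param res resolution in Angstrom setting the 1/e point.
#' @param ps pixel size in Angstrom.
#' @return a [voxel_grid] in DC-centered Fourier layout.
#' @export
gaussian_transfer <- function(shape, res, ps) {
  n <- as.integer(shape)
  if (n < 8L) stop("gaussian_transfer: shape must be at least 8")
  sigma <- gaussian_sigma(res, ps)
  if (res < 2 * ps)
    warning(sprintf(
      "gaussian_transfer: res %.3g A is beyond Nyquist (%.3g A); 1/e point outside the grid",
      res, 2 * ps))
  geo <- fourier_geometry(n)
  kv <- geo$r / n                      # cycles per voxel
  g <- exp(-2 * pi^2 * sigma^2 * kv^2)
  voxel_grid(array(g, dim = c(n, n, n)), ps, name = "gaussian_transfer")
}

#' Build the OTF from the dFSC volume and the Gaussian transfer
#'
#' Voxelwise product, normalized so the DC value is 1, clamped to \[0, 1\],
#' and zeroed beyond Nyquist.
#'
#' @param dfsc_volume rendered dFSC [voxel_grid] (DC-centered layout), e.g.
#'   `compute_dfsc(...)$volume`.
#' @param gauss Gaussian transfer [voxel_grid] from [gaussian_transfer].
#' @return an `otf_volume` (a [voxel_grid] subclass).
#' @export
build_otf <- function(dfsc_volume, gauss) {
  stopifnot(inherits(dfsc_volume, "voxel_grid"), inherits(gauss, "voxel_grid"))
  if (!identical(dim(dfsc_volume$data), dim(gauss$data)))
    stop("build_otf: shape mismatch")
  n <- dim(gauss$data)[1]
  geo <- fourier_geometry(n)
  prod <- dfsc_volume$data * gauss$data
  dc <- prod[geo$center, geo$center, geo$center]
  if (dc <= 0) stop("build_otf: DC value of the product is zero")
  v <- clamp(prod / dc, 0, 1)
  v[array(geo$shell > geo$nyq, dim = dim(v))] <- 0
  out <- voxel_grid(v, gauss$pixel_size, name = "otf")
  class(out) <- c("otf_volume", class(out))
  out
}

#' Point spread function of an OTF
#'
#' Real part of the inverse Fourier transform of the OTF, recentered so the
#' PSF peak sits at the central voxel; used to inspect real-space elongation
#' caused by missing Fourier cones.
#'
#' @param otf an `otf_volume` (or any DC-centered real [voxel_grid]).
#' @return a [voxel_grid] holding the centered PSF.
#' @export
psf_from_otf <- function(otf) {
  stopifnot(inherits(otf, "voxel_grid"))
  n3 <- length(otf$data)
  psf <- Re(stats::fft(ifftshift3(otf$data), inverse = TRUE)) / n3
  voxel_grid(fftshift3(psf), otf$pixel_size, name = "psf")
}
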