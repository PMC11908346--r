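#' Real-space density volume on a cubic grid
#'
#' Container for a real scalar field on an N x N x N grid with a physical
#' pixel size in Angstrom per voxel.  All pipeline stages operate on this
#' type; volumes are stored as base R 3D arrays (x fastest, matching the MRC
#' axis order).
#'
#' @param data numeric 3D array, cubic, N >= 8, all values finite.
#' @param pixel_size positive pixel size in Angstrom per voxel.
#' @param name free-text label carried through for provenance.
#' @return an object of class `voxel_grid` with fields `data`, `pixel_size`,
#'   `name`.
#' @export
voxel_grid <- function(data, pixel_size, name = "") {
  d <- dim(data)
  if (is.null(d) || length(d) != 3L)
    stop("voxel_grid: 'data' must be a 3D array")
  if (d[1] != d[2] || d[1] != d[3])
    stop(sprintf("voxel_grid: non-cubic volume (%d x %d x %d)",
                 d[1], d[2], d[3]))
  if (d[1] < 8L) stop("voxel_grid: grid must be at least 8^3")
  if (!is.numeric(data)) stop("voxel_grid: 'data' must be numeric")
  if (!all(is.finite(data))) stop("voxel_grid: non-finite values in data")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L ||
      !is.finite(pixel_size) || pixel_size <= 0)
    stop("voxel_grid: 'pixel_size' must be a positive scalar")
  structure(list(data = data, pixel_size = as.numeric(pixel_size),
                 name = as.character(name)),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  n <- dim(x$data)[1]
  cat(sprintf("<voxel_grid%s> %d^3 voxels, %.4g A/voxel, range [%.4g, %.4g]\n",
              if (nzchar(x$name)) paste0(" '", x$name, "'") else "",
              n, x$pixel_size, min(x$data), max(x$data)))
  invisible(x)
}

#' DC-centered complex Fourier volume
#'
#' Complex spectrum of a [voxel_grid] with the DC component at the central
#' voxel `floor(N/2)+1` on each axis.  The physical frequency of the voxel at
#' integer offset `v` from the center is `|v| / (N * pixel_size)` in 1/A.
#'
#' @param data complex 3D cubic array, DC-centered.
#' @param pixel_size pixel size (Angstrom) of the originating real grid.
#' @return an object of class `fourier_volume`.
#' @export
fourier_volume <- function(data, pixel_size) {
  d <- dim(data)
  if (is.null(d) || length(d) != 3L || d[1] != d[2] || d[1] != d[3])
    stop("fourier_volume: data must be a cubic 3D array")
  structure(list(data = data, pixel_size = as.numeric(pixel_size)),
            class = "fourier_volume")
}

#' @export
print.fourier_volume <- function(x, ...) {
  n <- dim(x$data)[1]
  cat(sprintf("<fourier_volume> %d^3 voxels, %.4g A/voxel, Nyquist %.4g 1/A\n",
              n, x$pixel_size, 1 / (2 * x$pixel_size)))
  invisible(x)
}

#' Forward 3D FFT with DC-centered layout
#'
#' Unnormalized forward transform (so Parseval reads
#' `sum(|g|^2) = sum(|fft3(g)|^2) / N^3`), with the spectrum shifted so the
#' DC term sits at the central voxel.
#'
#' @param grid a [voxel_grid].
#' @return a [fourier_volume].
#' @export
fft3 <- function(grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  fourier_volume(fftshift3(stats::fft(grid$data)), grid$pixel_size)
}

#' Inverse 3D FFT back to a real volume
#'
#' Inverts [fft3]; the imaginary part (at round-off level for Hermitian
#' inputs) is discarded.
#'
#' @param fv a [fourier_volume].
#' @param name label for the resulting grid.
#' @return a [voxel_grid].
#' @export
ifft3 <- function(fv, name = "") {
  stopifnot(inherits(fv, "fourier_volume"))
  n3 <- length(fv$data)
  voxel_grid(Re(stats::fft(ifftshift3(fv$data), inverse = TRUE)) / n3,
             fv$pixel_size, name = name)
}

#' Normalize a map to zero mean and unit standard deviation
#'
#' The convention of the widely used EMAN2 "normalize" processor: subtract
#' the mean over all voxels and divide by the standard deviation.
#'
#' @param grid a [voxel_grid] with non-zero variance.
#' @return a normalized [voxel_grid].
#' @export
normalize_map <- function(grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  s <- stats::sd(grid$data)
  if (s == 0) stop("normalize_map: constant map has zero variance")
  voxel_grid((grid$data - mean(grid$data)) / s, grid$pixel_size, grid$name)
}

#' Low-pass filter a map to a target resolution
#'
#' Radial Fourier filter with a raised-cosine transition band of width 2
#' Fourier voxels ending at `1/resolution`, so all amplitudes at spatial
#' frequencies at or beyond `1/resolution` are removed exactly.
#'
#' @param grid a [voxel_grid].
#' @param resolution target resolution in Angstrom; must be at least
#'   `2 * pixel_size` (Nyquist).
#' @return the filtered [voxel_grid].
#' @export
lowpass_filter <- function(grid, resolution) {
  stopifnot(inherits(grid, "voxel_grid"))
  ps <- grid$pixel_size
  if (resolution < 2 * ps)
    stop(sprintf("lowpass_filter: resolution %.3g A is below Nyquist %.3g A",
                 resolution, 2 * ps))
  n <- dim(grid$data)[1]
  geo <- fourier_geometry(n)
  f <- geo$r / (n * ps)              # 1/A
  fc <- 1 / resolution
  fl <- max(fc - 2 / (n * ps), 0)    # transition band: [fl, fc), 2 voxels
  h <- numeric(length(f))
  h[f <= fl] <- 1
  band <- f > fl & f < fc
  h[band] <- 0.5 * (1 + cos(pi * (f[band] - fl) / (fc - fl)))
  fv <- fft3(grid)
  fv$data <- fv$data * array(h, dim = dim(fv$data))
  ifft3(fv, name = grid$name)
}

#' Soft-edged bounding-sphere mask of the significant density
#'
#' Identifies all voxels above `threshold`, takes the center of their
#' bounding box, and builds a sphere that covers every suprathreshold voxel,
#' with a raised-cosine falloff from 1 to 0 over `edge_width` voxels outside
#' that radius.
#'
#' @param grid a [voxel_grid].
#' @param threshold density threshold defining the kept region.
#' @param edge_width soft-edge width in voxels (default 20).
#' @return a `mask_volume` (a [voxel_grid] subclass with an `edge_width`
#'   field), values in \[0, 1\].
#' @export
spherical_mask <- function(grid, threshold, edge_width = 20) {
  stopifnot(inherits(grid, "voxel_grid"))
  sel <- which(grid$data > threshold)
  if (length(sel) == 0L)
    stop("spherical_mask: no voxel above threshold")
  n <- dim(grid$data)[1]
  idx <- arrayInd(sel, dim(grid$data))
  ctr <- (apply(idx, 2, min) + apply(idx, 2, max)) / 2
  r0 <- sqrt(max(rowSums((sweep(idx, 2, ctr))^2)))
  ax <- seq_len(n)
  dx2 <- (ax - ctr[1])^2
  dy2 <- (ax - ctr[2])^2
  dz2 <- (ax - ctr[3])^2
  d <- sqrt(outer(outer(dx2, dy2, `+`), dz2, `+`))
  m <- array(0, dim = c(n, n, n))
  m[d <= r0] <- 1
  band <- d > r0 & d < r0 + edge_width
  m[band] <- 0.5 * (1 + cos(pi * (d[band] - r0) / edge_width))
  out <- voxel_grid(m, grid$pixel_size, name = "mask")
  out$edge_width <- edge_width
  class(out) <- c("mask_volume", class(out))
  out
}

#' Apply a mask to a map (voxelwise product)
#'
#' @param grid a [voxel_grid].
#' @param mask a mask [voxel_grid] of the same shape.
#' @return the masked [voxel_grid].
#' @export
apply_mask <- function(grid, mask) {
  stopifnot(inherits(grid, "voxel_grid"), inherits(mask, "voxel_grid"))
  if (!identical(dim(grid$data), dim(mask$data)))
    stop("apply_mask: shape mismatch between map and mask")
  voxel_grid(grid$data * mask$data, grid$pixel_size, grid$name)
}

#' Fourier amplitude volume for missing-cone inspection
#'
#' Returns `|fft3(grid)|` as a real DC-centered volume; rendering this at a
#' low contour level makes unsampled Fourier regions (missing cones) directly
#' visible.
#'
#' @param grid a [voxel_grid].
#' @return a [voxel_grid] of Fourier amplitudes (DC-centered layout).
#' @export
fourier_amplitude <- function(grid) {
  fv <- fft3(grid)
  voxel_grid(Mod(fv$data), grid$pixel_size, name = "amplitude")
}
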