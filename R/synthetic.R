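# Synthetic missing-cone test data.
#
# The pipeline is validated without any experimental download by emulating,
# at the volume level, what a preferred-orientation dataset does to a
# reconstruction: projections concentrated away from the pole leave a double
# cone of Fourier space unsampled (central-slice theorem), so the degraded
# map is the ideal map convolved with an anisotropic PSF.  The generator
# produces a blob phantom, orientation tables, the tilt-band particle
# filter, Fourier coverage weights, and noisy half-maps sharing the
# coverage.

#' Random blob phantom
#'
#' Sum of `n_blobs` axis-aligned anisotropic Gaussian blobs with random
#' centers (within the central 70% sphere), widths uniform in 1-3 voxels
#' (secondary-structure scale at ~1 A/voxel) and amplitudes in 0.5-1.5;
#' byte-reproducible from `seed`.
#'
#' @param shape grid size N (>= 32).
#' @param pixel_size pixel size in Angstrom (default 1).
#' @param n_blobs number of blobs (default 30).
#' @param seed RNG seed (default 0).
#' @return a [voxel_grid].
#' @export
make_phantom <- function(shape, pixel_size = 1, n_blobs = 30, seed = 0) {
  n <- as.integer(shape)
  if (n < 32L) stop("make_phantom: shape must be at least 32")
  vol <- array(0, dim = c(n, n, n))
  if (n_blobs > 0) {
    ctr <- (n + 1) / 2
    prm <- with_seed(seed, {
      list(cen = matrix(stats::runif(3 * n_blobs, ctr - 0.35 * n,
                                     ctr + 0.35 * n), ncol = 3),
           sig = matrix(stats::runif(3 * n_blobs, 1, 3), ncol = 3),
           amp = stats::runif(n_blobs, 0.5, 1.5))
    })
    ax <- seq_len(n)
    for (b in seq_len(n_blobs)) {
      gx <- exp(-(ax - prm$cen[b, 1])^2 / (2 * prm$sig[b, 1]^2))
      gy <- exp(-(ax - prm$cen[b, 2])^2 / (2 * prm$sig[b, 2]^2))
      gz <- exp(-(ax - prm$cen[b, 3])^2 / (2 * prm$sig[b, 3]^2))
      vol <- vol + prm$amp[b] * outer(outer(gx, gy), gz)
    }
  }
  voxel_grid(vol, pixel_size, name = sprintf("phantom_seed%d", seed))
}

new_orientation_table <- function(rot, tilt, psi) {
  df <- data.frame(rot = rot, tilt = tilt, psi = psi)
  if (any(df$tilt < 0 | df$tilt > 180))
    stop("orientation_table: tilt must be in [0, 180]")
  class(df) <- c("orientation_table", "data.frame")
  df
}

#' Projection direction vectors of an orientation table
#'
#' ZYZ intrinsic Euler convention: the projection direction is
#' `Rz(rot) Ry(tilt) Rz(psi) . z = (sin(tilt)cos(rot), sin(tilt)sin(rot), cos(tilt))`,
#' so `tilt` is exactly the angle to +z.
#'
#' @param table an `orientation_table`.
#' @return an n x 3 matrix of unit vectors.
#' @export
orientation_directions <- function(table) {
  tr <- table$tilt * pi / 180
  rr <- table$rot * pi / 180
  cbind(x = sin(tr) * cos(rr), y = sin(tr) * sin(rr), z = cos(tr))
}

#' Uniformly distributed particle orientations
#'
#' Directions uniform on the sphere (`tilt = acos(U(-1,1))`), rot and psi
#' uniform in (-180, 180\]; reproducible from `seed`.
#'
#' @param n number of rows (>= 1).
#' @param seed RNG seed.
#' @return an `orientation_table` data.frame with columns `rot`, `tilt`,
#'   `psi` in degrees.
#' @export
sample_uniform_orientations <- function(n, seed = 0) {
  if (n < 1) stop("sample_uniform_orientations: n must be >= 1")
  with_seed(seed, {
    z <- stats::runif(n, -1, 1)
    new_orientation_table(rot = stats::runif(n, -180, 180),
                          tilt = acos(z) * 180 / pi,
                          psi = stats::runif(n, -180, 180))
  })
}

#' Tilt-band orientation filter
#'
#' Keeps particles whose projection direction makes an angle with the z axis
#' in `[0, keep_low]` or `[keep_high, 180]` degrees (defaults 60/120),
#' emulating a dataset with a preferred orientation: for uniform input this
#' retains exactly half the particles and leaves a 30-degree missing double
#' cone about the Fourier z axis.
#'
#' @param table an `orientation_table`.
#' @param keep_low,keep_high band edges in degrees, `0 < keep_low <
#'   keep_high < 180`.
#' @return the filtered `orientation_table`, original row order preserved.
#' @export
filter_by_tilt <- function(table, keep_low = 60, keep_high = 120) {
  if (!(keep_low > 0 && keep_low < keep_high && keep_high < 180))
    stop("filter_by_tilt: need 0 < keep_low < keep_high < 180")
  keep <- table$tilt <= keep_low | table$tilt >= keep_high
  out <- table[keep, , drop = FALSE]
  if (nrow(out) == 0L)
    warning("filter_by_tilt: no orientation retained")
  class(out) <- c("orientation_table", "data.frame")
  out
}

#' Fourier sampling weights implied by an orientation set
#'
#' Central-slice model: each projection direction contributes a slab of
#' sampled Fourier voxels within `slab_halfwidth` voxels of the central
#' plane perpendicular to it; counts are normalized to a maximum of 1.
#'
#' @param table non-empty `orientation_table`.
#' @param shape grid size N.
#' @param slab_halfwidth slab half-thickness in voxels (default 1).
#' @return a [voxel_grid] of weights in \[0, 1\] (DC-centered layout,
#'   pixel_size 1).
#' @export
sampling_weight_volume <- function(table, shape, slab_halfwidth = 1) {
  if (nrow(table) == 0L) stop("sampling_weight_volume: empty table")
  n <- as.integer(shape)
  geo <- fourier_geometry(n)
  dirs <- orientation_directions(table)
  counts <- numeric(n^3)
  chunk <- 256L
  for (s in seq(1L, nrow(dirs), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(dirs))
    dd <- abs(geo$offsets %*% t(dirs[s:e, , drop = FALSE]))
    counts <- counts + rowSums(dd <= slab_halfwidth)
  }
  voxel_grid(array(counts / max(counts), dim = c(n, n, n)), 1,
             name = "sampling_weights")
}

#' Binary missing-cone mask in Fourier space
#'
#' Value 1 for voxels whose frequency direction lies strictly within
#' `half_angle` degrees of `axis` or its antipode (a double cone), 0
#' elsewhere; the DC voxel is 0.  Exactly centro-symmetric.
#'
#' @param shape grid size N.
#' @param half_angle cone half-angle in degrees, in (0, 90).
#' @param axis cone axis (default z).
#' @return a binary [voxel_grid] (DC-centered layout, pixel_size 1).
#' @export
missing_cone_mask <- function(shape, half_angle, axis = c(0, 0, 1)) {
  if (half_angle <= 0 || half_angle >= 90)
    stop("missing_cone_mask: half_angle must be in (0, 90)")
  n <- as.integer(shape)
  geo <- fourier_geometry(n)
  ax <- axis / sqrt(sum(axis^2))
  inside <- abs(drop(geo$khat %*% ax)) > cos(half_angle * pi / 180)
  inside[geo$r == 0] <- FALSE
  voxel_grid(array(as.numeric(inside), dim = c(n, n, n)), 1,
             name = "missing_cone")
}

#' Degrade a map by anisotropic Fourier coverage plus noise
#'
#' Builds two half-maps sharing the Fourier coverage weighting but carrying
#' independent white Gaussian noise, and their mean as the full map:
#' `half_i = IFFT( FFT(truth + noise_i) * coverage )`.  The noise is applied
#' before the coverage weighting because an experimental reconstruction has
#' no content of any kind - signal or noise - in unsampled Fourier regions;
#' its transform shows a genuinely empty cone.  `noise_sigma` is expressed
#' relative to the RMS of the truth map.
#'
#' @param truth ideal map ([voxel_grid]).
#' @param coverage Fourier weight volume (DC-centered, same shape), e.g.
#'   `1 - missing_cone_mask(...)` or a [sampling_weight_volume].
#' @param noise_sigma noise standard deviation relative to truth RMS (>= 0).
#' @param seed RNG seed; the two half-map noise fields are drawn
#'   sequentially from it.
#' @return a `degraded_set`: `truth`, `full`, `half1`, `half2`, `coverage`,
#'   `noise_sigma`, `seed`.  Invariant: `full = (half1 + half2) / 2`.
#' @export
degrade <- function(truth, coverage, noise_sigma = 0.5, seed = 0) {
  stopifnot(inherits(truth, "voxel_grid"), inherits(coverage, "voxel_grid"))
  if (!identical(dim(truth$data), dim(coverage$data)))
    stop("degrade: shape mismatch between truth and coverage")
  if (noise_sigma < 0) stop("degrade: noise_sigma must be >= 0")
  n <- dim(truth$data)[1]
  sig <- noise_sigma * sqrt(mean(truth$data^2))
  noise <- with_seed(seed, list(
    n1 = array(stats::rnorm(n^3, 0, sig), dim = dim(truth$data)),
    n2 = array(stats::rnorm(n^3, 0, sig), dim = dim(truth$data))))
  if (sig == 0) noise <- list(n1 = 0, n2 = 0)
  w <- coverage$data
  mk_half <- function(nz, label) {
    fv <- fft3(voxel_grid(truth$data + nz, truth$pixel_size))
    fv$data <- fv$data * w
    out <- ifft3(fv, name = label)
    out
  }
  h1 <- mk_half(noise$n1, "half1")
  h2 <- mk_half(noise$n2, "half2")
  full <- voxel_grid((h1$data + h2$data) / 2, truth$pixel_size, name = "full")
  structure(list(truth = truth, full = full, half1 = h1, half2 = h2,
                 coverage = coverage, noise_sigma = noise_sigma,
                 seed = seed),
            class = "degraded_set")
}

#' Write an orientation table as STAR-like text
#'
#' Minimal `loop_` block with `_rlnAngleRot`, `_rlnAngleTilt`,
#' `_rlnAnglePsi` columns for interoperability with common particle-star
#' tooling.
#'
#' @param table an `orientation_table`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_orientations <- function(table, path) {
  lines <- c("", "data_particles", "", "loop_",
             "_rlnAngleRot #1", "_rlnAngleTilt #2", "_rlnAnglePsi #3",
             sprintf("%.6f %.6f %.6f", table$rot, table$tilt, table$psi))
  writeLines(lines, path)
  invisible(path)
}

#' Read an orientation table written by [write_orientations]
#'
#' @param path path to a STAR-like text file with rot/tilt/psi angle
#'   columns.
#' @return an `orientation_table`.
#' @export
read_orientations <- function(path) {
  if (!file.exists(path)) stop(sprintf("read_orientations: file not found: %s", path))
  lines <- readLines(path)
  cols <- grep("^_rln", lines)
  if (length(cols) == 0L) stop("read_orientations: no _rln columns found")
  names <- sub("\\s*#.*$", "", lines[cols])
  body <- lines[seq(max(cols) + 1L, length(lines))]
  body <- body[nzchar(trimws(body))]
  vals <- do.call(rbind, lapply(strsplit(trimws(body), "\\s+"), as.numeric))
  colnames(vals) <- names
  new_orientation_table(rot = vals[, "_rlnAngleRot"],
                        tilt = vals[, "_rlnAngleTilt"],
                        psi = vals[, "_rlnAnglePsi"])
}
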