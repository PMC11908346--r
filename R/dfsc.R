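# Directional Fourier shell correlation (dFSC).
#
# Conventional FSC correlates two half-map spectra over full spherical
# shells; with preferred particle orientation that average hides strongly
# direction-dependent information content.  dFSC restricts each correlation
# to the voxels of a cone about a sampled direction, producing one FSC curve
# per direction and, from all of them, a 3D Fourier-space rendering of local
# map consistency.

#' Evenly distributed directions from a Fibonacci spherical lattice
#'
#' Deterministic golden-angle spiral: `z_i = 1 - (2i+1)/n` for
#' `i = 0..n-1` (so z stays inside (-1, 1)) and azimuth `i * pi * (3 - sqrt(5))`.
#'
#' @param n number of directions (>= 1); the pipeline default is 500.
#' @return an `n x 3` matrix of unit row vectors.
#' @export
fibonacci_directions <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("fibonacci_directions: n must be a positive integer")
  n <- as.integer(n)
  i <- seq_len(n) - 1
  z <- 1 - (2 * i + 1) / n
  rho <- sqrt(pmax(1 - z^2, 0))
  phi <- i * pi * (3 - sqrt(5))
  v <- cbind(x = rho * cos(phi), y = rho * sin(phi), z = z)
  v / sqrt(rowSums(v^2))
}

# Shell-wise FSC over an arbitrary Fourier-voxel subset.
# a, p1, p2: Re(f1 * Conj(f2)), |f1|^2, |f2|^2 as vectors; member: logical
# subset; shell: integer shell index per voxel; nyq: last reported shell.
# Distinguishes two degeneracies: `empty` shells contain no voxels at all
# (geometry - nothing is knowable there), while `zero_power` shells have
# voxels but no signal in at least one input (a measured zero correlation,
# e.g. inside a missing cone).  Both report correlation 0.
shell_fsc <- function(a, p1, p2, member, shell, nyq) {
  keep <- member & shell >= 1L & shell <= nyq
  sh <- shell[keep]
  agg <- function(v) {
    s <- numeric(nyq)
    t <- rowsum(v[keep], sh)
    s[as.integer(rownames(t))] <- t
    s
  }
  num <- agg(a)
  d1 <- agg(p1)
  d2 <- agg(p2)
  nvox <- integer(nyq)
  tb <- table(sh)
  nvox[as.integer(names(tb))] <- as.integer(tb)
  den <- sqrt(d1 * d2)
  empty <- nvox == 0L
  zero_power <- !empty & den <= 0
  ok <- !empty & !zero_power
  fsc <- numeric(nyq)
  fsc[ok] <- num[ok] / den[ok]
  list(fsc = clamp(fsc, -1, 1), n_voxels = nvox, empty = empty,
       zero_power = zero_power)
}

new_fsc_curve <- function(frequencies, correlations, shell_width, n_voxels,
                          empty, pixel_size,
                          zero_power = rep(FALSE, length(correlations))) {
  structure(list(frequencies = frequencies, correlations = correlations,
                 shell_width = shell_width, n_voxels = n_voxels,
                 empty = empty, zero_power = zero_power,
                 pixel_size = pixel_size),
            class = "fsc_curve")
}

#' @export
print.fsc_curve <- function(x, ...) {
  cat(sprintf("<fsc_curve> %d shells to %.4g 1/A; FSC range [%.3f, %.3f]\n",
              length(x$frequencies), max(x$frequencies),
              min(x$correlations), max(x$correlations)))
  invisible(x)
}

check_same_grid <- function(f1, f2, what) {
  if (!identical(dim(f1$data), dim(f2$data)))
    stop(sprintf("%s: shape mismatch between inputs", what))
  if (abs(f1$pixel_size - f2$pixel_size) > 1e-9 * f1$pixel_size)
    stop(sprintf("%s: pixel size mismatch (%g vs %g)", what,
                 f1$pixel_size, f2$pixel_size))
}

#' FSC restricted to a cone of Fourier directions
#'
#' Per radial shell, correlates the voxels whose frequency vector (or its
#' Friedel mate) lies within `apex_angle / 2` of `direction`.  `apex_angle`
#' is the full cone opening, so the pipeline default of 40 degrees keeps
#' voxels within 20 degrees of the axis.
#'
#' @param f1,f2 [fourier_volume]s on the same grid.
#' @param direction 3-vector cone axis (normalized internally).
#' @param apex_angle full cone opening angle in degrees, in (0, 180].
#' @param warn warn when shells have no voxels or zero power (default TRUE);
#'   such shells report correlation 0 and are flagged.
#' @return an `fsc_curve` with fields `frequencies` (1/A), `correlations`,
#'   `shell_width`, `n_voxels`, `empty` (shell contains no voxels) and
#'   `zero_power` (voxels present but no measurable signal).
#' @export
conical_fsc <- function(f1, f2, direction, apex_angle = 40, warn = TRUE) {
  stopifnot(inherits(f1, "fourier_volume"), inherits(f2, "fourier_volume"))
  check_same_grid(f1, f2, "conical_fsc")
  if (apex_angle <= 0 || apex_angle > 180)
    stop("conical_fsc: apex_angle must be in (0, 180]")
  d <- direction / sqrt(sum(direction^2))
  n <- dim(f1$data)[1]
  geo <- fourier_geometry(n)
  cosmin <- cos(apex_angle / 2 * pi / 180)
  member <- abs(drop(geo$khat %*% d)) >= cosmin - 1e-12
  a <- Re(f1$data * Conj(f2$data))
  res <- shell_fsc(as.vector(a), as.vector(Mod(f1$data)^2),
                   as.vector(Mod(f2$data)^2), member, geo$shell, geo$nyq)
  if (warn && any(res$empty | res$zero_power))
    warning(sprintf("conical_fsc: %d unsampled and %d zero-power shell(s); set to 0",
                    sum(res$empty), sum(res$zero_power)))
  freq <- seq_len(geo$nyq) / (n * f1$pixel_size)
  new_fsc_curve(freq, res$fsc, 1 / (n * f1$pixel_size), res$n_voxels,
                res$empty, f1$pixel_size, res$zero_power)
}

#' Conventional spherical-shell FSC
#'
#' @param f1,f2 [fourier_volume]s on the same grid.
#' @return an `fsc_curve` (see [conical_fsc]).
#' @export
global_fsc <- function(f1, f2) {
  stopifnot(inherits(f1, "fourier_volume"), inherits(f2, "fourier_volume"))
  check_same_grid(f1, f2, "global_fsc")
  n <- dim(f1$data)[1]
  geo <- fourier_geometry(n)
  a <- Re(f1$data * Conj(f2$data))
  res <- shell_fsc(as.vector(a), as.vector(Mod(f1$data)^2),
                   as.vector(Mod(f2$data)^2), rep(TRUE, n^3), geo$shell,
                   geo$nyq)
  freq <- seq_len(geo$nyq) / (n * f1$pixel_size)
  new_fsc_curve(freq, res$fsc, 1 / (n * f1$pixel_size), res$n_voxels,
                res$empty, f1$pixel_size, res$zero_power)
}

#' Directional FSC over a set of cone directions
#'
#' Computes one conical FSC curve per direction (default: 500 Fibonacci
#' directions, 40-degree cones) from two unfiltered half-maps and renders the
#' 3D dFSC volume used to build the optical transfer function.
#'
#' @param half1,half2 [voxel_grid] half-maps on the same grid.
#' @param mask optional mask [voxel_grid] applied to both halves before
#'   transforming.
#' @param n_dirs number of Fibonacci directions (default 500).
#' @param apex_angle full cone opening in degrees (default 40).
#' @return a `dfsc_result` with fields `directions` (n x 3), `frequencies`,
#'   `fsc` (shells x directions matrix), `n_voxels`, `empty`, `zero_power`,
#'   `apex_angle`, `volume` (rendered dFSC as a DC-centered [voxel_grid]),
#'   `pixel_size`.
#' @export
compute_dfsc <- function(half1, half2, mask = NULL, n_dirs = 500,
                         apex_angle = 40) {
  stopifnot(inherits(half1, "voxel_grid"), inherits(half2, "voxel_grid"))
  if (!identical(dim(half1$data), dim(half2$data)))
    stop("compute_dfsc: half-map shape mismatch")
  if (!is.null(mask)) {
    half1 <- apply_mask(half1, mask)
    half2 <- apply_mask(half2, mask)
  }
  f1 <- fft3(half1)
  f2 <- fft3(half2)
  n <- dim(f1$data)[1]
  geo <- fourier_geometry(n)
  dirs <- fibonacci_directions(n_dirs)
  a <- as.vector(Re(f1$data * Conj(f2$data)))
  p1 <- as.vector(Mod(f1$data)^2)
  p2 <- as.vector(Mod(f2$data)^2)
  cosmin <- cos(apex_angle / 2 * pi / 180)
  fsc <- matrix(0, nrow = geo$nyq, ncol = n_dirs)
  nvox <- matrix(0L, nrow = geo$nyq, ncol = n_dirs)
  empty <- matrix(FALSE, nrow = geo$nyq, ncol = n_dirs)
  zero_power <- matrix(FALSE, nrow = geo$nyq, ncol = n_dirs)
  n_deg <- 0L
  for (j in seq_len(n_dirs)) {
    member <- abs(drop(geo$khat %*% dirs[j, ])) >= cosmin - 1e-12
    res <- shell_fsc(a, p1, p2, member, geo$shell, geo$nyq)
    fsc[, j] <- res$fsc
    nvox[, j] <- res$n_voxels
    empty[, j] <- res$empty
    zero_power[, j] <- res$zero_power
    n_deg <- n_deg + sum(res$empty | res$zero_power)
  }
  if (n_deg > 0L)
    warning(sprintf("compute_dfsc: %d conical shell(s) unsampled or with zero power; set to 0",
                    n_deg))
  vol <- render_dfsc_volume(fsc, dirs, n, half1$pixel_size, apex_angle,
                            empty = empty)
  structure(list(directions = dirs,
                 frequencies = seq_len(geo$nyq) / (n * half1$pixel_size),
                 fsc = fsc, n_voxels = nvox, empty = empty,
                 zero_power = zero_power, apex_angle = apex_angle,
                 volume = vol, pixel_size = half1$pixel_size),
            class = "dfsc_result")
}

#' @export
print.dfsc_result <- function(x, ...) {
  cat(sprintf("<dfsc_result> %d directions, apex %.1f deg, %d shells\n",
              nrow(x$directions), x$apex_angle, nrow(x$fsc)))
  invisible(x)
}

#' Render per-direction FSC curves as a 3D Fourier-space volume
#'
#' Each Fourier voxel takes the weighted average, over the directions whose
#' cones contain it, of that direction's curve at the voxel's radial shell.
#' Weights are the cosine of the angular distance to each containing cone
#' axis, renormalized to sum to 1; the rare voxels covered by no cone take
#' the value of the angularly nearest direction.  Values are clamped to
#' \[0, 1\] (the volume feeds a nonnegative transfer function), the DC voxel
#' takes the directional mean of the first shell and voxels beyond Nyquist
#' are 0.
#'
#' @param fsc shells x directions matrix of correlations.
#' @param directions matching n x 3 matrix of unit direction vectors.
#' @param shape grid size N.
#' @param pixel_size pixel size in Angstrom.
#' @param apex_angle full cone opening in degrees.
#' @param empty optional logical matrix matching `fsc` flagging shells with
#'   no measurable correlation (no voxels / zero power); flagged entries are
#'   excluded from the averages rather than counted as zeros.
#' @return a [voxel_grid] in DC-centered Fourier layout.
#' @export
render_dfsc_volume <- function(fsc, directions, shape, pixel_size,
                               apex_angle = 40, empty = NULL) {
  n <- as.integer(shape)
  geo <- fourier_geometry(n)
  nyq <- geo$nyq
  if (nrow(fsc) != nyq)
    stop("render_dfsc_volume: curve length does not match grid Nyquist")
  if (ncol(fsc) != nrow(directions))
    stop("render_dfsc_volume: curves/directions count mismatch")
  if (is.null(empty))
    empty <- matrix(FALSE, nrow = nyq, ncol = ncol(fsc))
  cosmin <- cos(apex_angle / 2 * pi / 180)
  nv <- n^3
  num <- numeric(nv)
  den <- numeric(nv)
  inband <- geo$shell >= 1L & geo$shell <= nyq
  sh <- geo$shell
  for (j in seq_len(nrow(directions))) {
    dt <- abs(drop(geo$khat %*% directions[j, ]))
    m <- which(dt >= cosmin - 1e-12 & inband)
    m <- m[!empty[sh[m], j]]
    w <- dt[m]
    num[m] <- num[m] + w * fsc[sh[m], j]
    den[m] <- den[m] + w
  }
  val <- numeric(nv)
  cov <- den > 0
  val[cov] <- num[cov] / den[cov]
  unc <- which(!cov & inband)
  if (length(unc) > 0L) {
    # fall back to the angularly nearest direction with a measured value
    dots <- abs(geo$khat[unc, , drop = FALSE] %*% t(directions))
    for (i in seq_along(unc)) {
      ok <- which(!empty[sh[unc[i]], ])
      if (length(ok) > 0L)
        val[unc[i]] <- fsc[sh[unc[i]], ok[which.max(dots[i, ok])]]
    }
  }
  val[!inband] <- 0
  dc1 <- !empty[1, ]                   # DC: no direction is defined
  val[geo$shell == 0L] <- if (any(dc1)) mean(fsc[1, dc1]) else 0
  voxel_grid(array(clamp(val, 0, 1), dim = c(n, n, n)), pixel_size,
             name = "dfsc_volume")
}

#' Resolution at an FSC threshold crossing
#'
#' Reciprocal of the frequency of the first downward crossing of `threshold`,
#' linearly interpolated between shell centers.  A curve that never drops
#' below the threshold reports the Nyquist resolution `2 * pixel_size`; a
#' curve that starts below it reports the coarsest shell's resolution with a
#' warning.
#'
#' @param curve an `fsc_curve`.
#' @param threshold FSC threshold in (0, 1); 0.143 for half-map curves, 0.5
#'   for map-to-model comparisons.
#' @return resolution in Angstrom.
#' @export
estimate_resolution <- function(curve, threshold = 0.143) {
  stopifnot(inherits(curve, "fsc_curve"))
  if (length(curve$frequencies) == 0L)
    stop("estimate_resolution: empty curve")
  if (threshold <= 0 || threshold >= 1)
    stop("estimate_resolution: threshold must be in (0, 1)")
  keep <- if (is.null(curve$empty)) rep(TRUE, length(curve$frequencies))
          else !curve$empty
  if (!any(keep)) {
    warning("estimate_resolution: all shells empty; reporting coarsest shell")
    return(1 / curve$frequencies[1])
  }
  cc <- curve$correlations[keep]      # empty shells carry no data
  f <- curve$frequencies[keep]
  below <- which(cc < threshold)
  if (length(below) == 0L) return(1 / max(f))
  i <- below[1]
  if (i == 1L) {
    warning("estimate_resolution: curve starts below threshold; reporting coarsest shell")
    return(1 / f[1])
  }
  f_star <- f[i - 1] + (cc[i - 1] - threshold) / (cc[i - 1] - cc[i]) *
    (f[i] - f[i - 1])
  1 / f_star
}

mean_curve <- function(dfsc, cols) {
  new_fsc_curve(dfsc$frequencies,
                rowMeans(dfsc$fsc[, cols, drop = FALSE]),
                dfsc$frequencies[1], rowSums(dfsc$n_voxels[, cols, drop = FALSE]),
                apply(dfsc$empty[, cols, drop = FALSE], 1, all),
                dfsc$pixel_size,
                apply(dfsc$zero_power[, cols, drop = FALSE], 1, all))
}

#' Average dFSC inside versus outside a cone of directions
#'
#' Splits the sampled directions by angular distance to `axis` (or its
#' antipode), averages the curves of each partition and reports threshold
#' resolutions, mirroring the standard inside-/outside-missing-cone
#' comparison.
#'
#' @param dfsc a `dfsc_result`.
#' @param axis cone axis (3-vector, normalized internally).
#' @param half_angle cone half-angle in degrees, in (0, 90).
#' @param threshold FSC threshold for the resolution estimates.
#' @return a `cone_partition_stats` list: `axis`, `half_angle`,
#'   `inside`/`outside` (direction index vectors), `mean_curve_inside`,
#'   `mean_curve_outside`, `mean_curve_overall`, `resolution_inside`,
#'   `resolution_outside`, `resolution_overall`.
#' @export
cone_partition_stats <- function(dfsc, axis = c(0, 0, 1), half_angle = 30,
                                 threshold = 0.143) {
  stopifnot(inherits(dfsc, "dfsc_result"))
  if (half_angle <= 0 || half_angle >= 90)
    stop("cone_partition_stats: half_angle must be in (0, 90)")
  ax <- axis / sqrt(sum(axis^2))
  ang <- abs(drop(dfsc$directions %*% ax))
  inside <- which(ang >= cos(half_angle * pi / 180))
  outside <- setdiff(seq_len(nrow(dfsc$directions)), inside)
  if (length(inside) == 0L)
    stop("cone_partition_stats: inside partition is empty")
  if (length(outside) == 0L)
    stop("cone_partition_stats: outside partition is empty")
  ci <- mean_curve(dfsc, inside)
  co <- mean_curve(dfsc, outside)
  ca <- mean_curve(dfsc, seq_len(nrow(dfsc$directions)))
  structure(list(axis = ax, half_angle = half_angle,
                 inside = inside, outside = outside,
                 mean_curve_inside = ci, mean_curve_outside = co,
                 mean_curve_overall = ca,
                 resolution_inside = estimate_resolution(ci, threshold),
                 resolution_outside = estimate_resolution(co, threshold),
                 resolution_overall = estimate_resolution(ca, threshold)),
            class = "cone_partition_stats")
}
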