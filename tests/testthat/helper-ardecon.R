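# Fixtures are generated in code; nothing is read from disk.

# all-pass Fourier coverage
iso_cov <- function(n) voxel_grid(array(1, c(n, n, n)), 1, name = "iso")

# isotropic band-limited truth: white noise low-passed to `res`; unlike the
# blob phantom this has no genuine directional structure, so it is the right
# world for isotropy properties.
band_truth <- function(n, seed, res = 3.2) {
  set.seed(seed)
  lowpass_filter(voxel_grid(array(rnorm(n^3), c(n, n, n)), 1,
                            name = "band_truth"), res)
}

# apply k -> -k in the DC-centered layout (DC voxel stays fixed)
centro_flip <- function(x) {
  n <- dim(x)[1]
  p <- ((2 * (floor(n / 2) + 1) - seq_len(n) - 1) %% n) + 1
  x[p, p, p]
}

# fsc_curve constructor for hand-built curves
make_curve <- function(freq, cc, empty = rep(FALSE, length(cc)), ps = 1) {
  ardecon:::new_fsc_curve(freq, cc, if (length(freq) > 1) diff(freq[1:2])
                          else freq[1],
                          rep(1L, length(cc)), empty, ps)
}

# Brute-force per-voxel conical FSC oracle: explicit triple loop, scalar
# accumulation, independent of the vectorized implementation.
oracle_conical_fsc <- function(f1, f2, direction, apex_angle) {
  d <- direction / sqrt(sum(direction^2))
  n <- dim(f1$data)[1]
  c0 <- floor(n / 2) + 1
  nyq <- floor(n / 2)
  num <- numeric(nyq); p1 <- numeric(nyq); p2 <- numeric(nyq)
  nvox <- integer(nyq)
  half <- apex_angle / 2 * pi / 180
  for (iz in 1:n) for (iy in 1:n) for (ix in 1:n) {
    k <- c(ix - c0, iy - c0, iz - c0)
    r <- sqrt(sum(k^2))
    s <- round(r)
    if (s < 1 || s > nyq) next
    ang <- acos(min(1, abs(sum(k * d)) / r))
    if (ang > half + 1e-12) next
    a <- f1$data[ix, iy, iz]; b <- f2$data[ix, iy, iz]
    num[s] <- num[s] + Re(a * Conj(b))
    p1[s] <- p1[s] + Mod(a)^2
    p2[s] <- p2[s] + Mod(b)^2
    nvox[s] <- nvox[s] + 1L
  }
  den <- sqrt(p1 * p2)
  fsc <- numeric(nyq)
  ok <- den > 0
  fsc[ok] <- num[ok] / den[ok]
  list(fsc = pmin(pmax(fsc, -1), 1), n_voxels = nvox, empty = !ok | nvox == 0L)
}

# per-direction threshold resolutions from a dfsc_result
dir_resolutions <- function(dd, threshold = 0.143) {
  vapply(seq_len(ncol(dd$fsc)), function(j) {
    cv <- ardecon:::new_fsc_curve(dd$frequencies, dd$fsc[, j],
                                  dd$frequencies[1], dd$n_voxels[, j],
                                  dd$empty[, j], dd$pixel_size)
    suppressWarnings(estimate_resolution(cv, threshold))
  }, numeric(1))
}

# ---- shared missing-cone recovery experiment (acceptance criteria 5 & 8) --
# 64^3 blob phantom, 30-degree missing cone, relative noise 0.5, pipeline
# defaults (500 directions, apex 40, smoothing 0.5, nonlinearity 1e4).
# Memoized so several acceptance tests can share one run per seed.
.acc_env <- new.env(parent = emptyenv())

recovery_run <- function(seed) {
  key <- paste0("seed", seed)
  if (!is.null(.acc_env[[key]])) return(.acc_env[[key]])
  n <- 64L
  truth <- make_phantom(n, 1, 30, seed = seed)
  cone <- missing_cone_mask(n, 30)
  cov <- voxel_grid(1 - cone$data, 1, name = "coverage")
  ds <- degrade(truth, cov, 0.5, seed = seed)
  res <- suppressWarnings(run_ardecon(ds$half1, ds$half2, ds$full))
  geo <- ardecon:::fourier_geometry(n)
  band <- geo$shell >= 4L & geo$shell <= 28L
  inside <- as.vector(cone$data) > 0.5
  amp_ratio <- function(m) {
    a <- as.vector(fourier_amplitude(m)$data)
    mean(a[inside & band]) / mean(a[!inside & band])
  }
  m2t_stats <- function(m) {
    dd <- suppressWarnings(compute_dfsc(normalize_map(m),
                                        normalize_map(truth), n_dirs = 500))
    st <- suppressWarnings(cone_partition_stats(dd, c(0, 0, 1), 30, 0.5))
    list(mean_inside = mean(st$mean_curve_inside$correlations),
         gap = st$resolution_inside - st$resolution_outside)
  }
  before <- m2t_stats(ds$full)
  after <- m2t_stats(res$decon$map)
  out <- list(ratio_before = amp_ratio(ds$full),
              ratio_after = amp_ratio(res$decon$map),
              dfsc_in_before = before$mean_inside,
              dfsc_in_after = after$mean_inside,
              gap_before = before$gap, gap_after = after$gap,
              trace = res$decon$objective_trace,
              iterations = res$decon$iterations_run)
  .acc_env[[key]] <- out
  out
}
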