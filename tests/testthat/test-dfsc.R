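# Directional FSC: direction sampling, conical correlation, rendering,
# resolution estimation, cone partitions.

test_that("fibonacci_directions yields unit vectors with near-ideal packing", {
  d500 <- fibonacci_directions(500)
  expect_equal(nrow(d500), 500)
  expect_true(all(abs(sqrt(rowSums(d500^2)) - 1) < 1e-9))

  d2 <- fibonacci_directions(2)
  expect_true(all(abs(sqrt(rowSums(d2^2)) - 1) < 1e-9))

  # minimum pairwise angle within 20% of the uniform-packing ideal
  d <- fibonacci_directions(1000)
  cosang <- d %*% t(d)
  diag(cosang) <- -1
  min_angle <- acos(max(pmin(cosang, 1)))
  ideal <- sqrt(8 * pi / (sqrt(3) * 1000))
  expect_gt(min_angle, 0.8 * ideal)
  expect_lt(min_angle, 1.2 * ideal)

  expect_error(fibonacci_directions(0))
})

test_that("conical_fsc matches the brute-force per-voxel oracle to 1e-10", {
  set.seed(10)
  g1 <- voxel_grid(array(rnorm(16^3), c(16, 16, 16)), 1)
  g2 <- voxel_grid(array(rnorm(16^3), c(16, 16, 16)), 1)
  f1 <- fft3(g1); f2 <- fft3(g2)
  dirs <- fibonacci_directions(5)
  for (j in 1:5) {
    got <- suppressWarnings(conical_fsc(f1, f2, dirs[j, ], 40, warn = FALSE))
    want <- oracle_conical_fsc(f1, f2, dirs[j, ], 40)
    expect_identical(got$n_voxels, want$n_voxels)
    expect_lt(max(abs(got$correlations - want$fsc)), 1e-10)
  }
})

test_that("conical_fsc self-correlation is 1 and sign flip gives -1", {
  set.seed(11)
  g <- voxel_grid(array(rnorm(16^3), c(16, 16, 16)), 1)
  f <- fft3(g)
  cv <- suppressWarnings(conical_fsc(f, f, c(0, 0, 1), 40, warn = FALSE))
  expect_lt(max(abs(cv$correlations[!cv$empty] - 1)), 1e-10)

  fneg <- fourier_volume(-f$data, 1)
  cvn <- suppressWarnings(conical_fsc(f, fneg, c(0, 0, 1), 40, warn = FALSE))
  expect_lt(max(abs(cvn$correlations[!cvn$empty] + 1)), 1e-10)
})

test_that("independent white-noise halves decorrelate within the sampling bound", {
  set.seed(12)
  f1 <- fft3(voxel_grid(array(rnorm(32^3), c(32, 32, 32)), 1))
  f2 <- fft3(voxel_grid(array(rnorm(32^3), c(32, 32, 32)), 1))
  cv <- suppressWarnings(conical_fsc(f1, f2, c(0, 0, 1), 40, warn = FALSE))
  ok <- !cv$empty & cv$n_voxels > 0
  expect_true(all(abs(cv$correlations[ok]) <= 3 / sqrt(cv$n_voxels[ok])))
})

test_that("compute_dfsc of identical halves is 1 everywhere measurable", {
  g <- make_phantom(32, 1, 15, seed = 3)
  dd <- suppressWarnings(compute_dfsc(g, g, n_dirs = 60))
  expect_equal(nrow(dd$directions), 60)
  expect_lt(max(abs(dd$fsc[!dd$empty] - 1)), 1e-9)
  expect_true(all(dd$volume$data >= 0 & dd$volume$data <= 1))
})

test_that("a unity mask changes nothing", {
  g1 <- make_phantom(32, 1, 15, seed = 4)
  ds <- degrade(g1, iso_cov(32), 0.5, seed = 4)
  m1 <- voxel_grid(array(1, c(32, 32, 32)), 1)
  a <- suppressWarnings(compute_dfsc(ds$half1, ds$half2, n_dirs = 40))
  b <- suppressWarnings(compute_dfsc(ds$half1, ds$half2, mask = m1,
                                     n_dirs = 40))
  expect_equal(a$fsc, b$fsc, tolerance = 1e-12)
})

test_that("isotropic noise gives < 10% spread of per-direction resolutions", {
  for (seed in 0:4) {
    truth <- band_truth(64, 100 + seed)
    ds <- degrade(truth, iso_cov(64), 0.4, seed = seed)
    dd <- suppressWarnings(compute_dfsc(ds$half1, ds$half2, n_dirs = 150))
    rs <- dir_resolutions(dd)
    expect_lt(max(rs) - min(rs), 0.10 * mean(rs))
  }
})

test_that("missing-cone degradation resolves worse inside the cone (all seeds)", {
  n <- 48
  cone <- missing_cone_mask(n, 30)
  cov <- voxel_grid(1 - cone$data, 1)
  for (seed in 0:4) {
    truth <- make_phantom(n, 1, 40, seed = seed)
    ds <- degrade(truth, cov, 0.5, seed = seed)
    dd <- suppressWarnings(compute_dfsc(ds$half1, ds$half2, n_dirs = 150))
    # directions whose whole 20-degree cone is inside the missing cone
    # cannot be resolved at all
    st10 <- suppressWarnings(cone_partition_stats(dd, c(0, 0, 1), 10, 0.143))
    expect_gt(st10$resolution_inside, st10$resolution_outside)
    # over the full 30-degree partition boundary cones reach sampled
    # voxels, so compare information content rather than crossings
    st30 <- suppressWarnings(cone_partition_stats(dd, c(0, 0, 1), 30, 0.143))
    expect_lt(mean(st30$mean_curve_inside$correlations),
              mean(st30$mean_curve_outside$correlations))
  }
})

test_that("render_dfsc_volume handles constant curves and stays centro-symmetric", {
  n <- 32
  geo <- ardecon:::fourier_geometry(n)
  dirs <- fibonacci_directions(60)
  ones <- matrix(1, nrow = geo$nyq, ncol = 60)
  v1 <- render_dfsc_volume(ones, dirs, n, 1)
  inband <- array(geo$shell <= geo$nyq, c(n, n, n))
  expect_true(all(v1$data[inband] == 1))
  expect_true(all(v1$data[!inband] == 0))

  v0 <- render_dfsc_volume(ones * 0, dirs, n, 1)
  expect_true(all(v0$data == 0))

  # two antipodal directions with different curves: Friedel handling must
  # still give an exactly centro-symmetric rendering
  dd <- rbind(c(0, 0, 1), c(0, 0, -1))
  cm <- cbind(seq(1, 0, length.out = geo$nyq),
              seq(0.5, 0.2, length.out = geo$nyq))
  v <- render_dfsc_volume(cm, dd, n, 1)
  expect_lt(max(abs(v$data - centro_flip(v$data))), 1e-6)
})

test_that("global FSC equals the directional mean for isotropic data", {
  truth <- band_truth(64, 100)
  ds <- degrade(truth, iso_cov(64), 0.5, seed = 9)
  dd <- suppressWarnings(compute_dfsc(ds$half1, ds$half2, n_dirs = 500))
  gf <- global_fsc(fft3(ds$half1), fft3(ds$half2))
  covered <- which(apply(dd$n_voxels > 0, 1, all))
  expect_lt(max(abs(rowMeans(dd$fsc) - gf$correlations)[covered]), 0.05)
})

test_that("global_fsc identities: self = 1, disjoint support = 0", {
  set.seed(13)
  g <- voxel_grid(array(rnorm(16^3), c(16, 16, 16)), 1)
  f <- fft3(g)
  gf <- suppressWarnings(global_fsc(f, f))
  expect_lt(max(abs(gf$correlations[!gf$empty] - 1)), 1e-10)

  a <- array(0, c(16, 16, 16)); a[1:8, , ] <- rnorm(8 * 256)
  b <- array(0, c(16, 16, 16)); b[9:16, , ] <- rnorm(8 * 256)
  # disjoint Fourier support: correlate band-separated spectra instead
  fa <- fourier_volume(array(complex(real = as.vector(a)), c(16, 16, 16)), 1)
  fb <- fourier_volume(array(complex(real = as.vector(b)), c(16, 16, 16)), 1)
  gfo <- suppressWarnings(global_fsc(fa, fb))
  expect_true(all(abs(gfo$correlations) < 1e-12))

  expect_error(global_fsc(f, fft3(voxel_grid(array(1:8^3, c(8, 8, 8)), 1))),
               "shape")
})

test_that("estimate_resolution interpolates crossings and handles edge cases", {
  cv <- make_curve(c(0.1, 0.2, 0.3), c(1.0, 0.5, 0.0))
  expect_equal(estimate_resolution(cv, 0.143), 3.684, tolerance = 1e-3)
  expect_equal(estimate_resolution(cv, 0.5), 5.0, tolerance = 1e-10)

  flat <- make_curve(seq(1, 8) / 16, rep(1, 8))   # never crosses, ps = 1
  expect_equal(estimate_resolution(flat, 0.143), 2.0)

  low <- make_curve(c(0.1, 0.2), c(0.05, 0.01))
  expect_warning(r <- estimate_resolution(low, 0.143), "below threshold")
  expect_equal(r, 10)

  expect_error(estimate_resolution(make_curve(numeric(0), numeric(0)), 0.143),
               "empty")
  expect_error(estimate_resolution(cv, 1.5), "threshold")
})

test_that("cone_partition_stats splits directions and propagates curves", {
  g <- make_phantom(32, 1, 15, seed = 5)
  dd <- suppressWarnings(compute_dfsc(g, g, n_dirs = 100))
  st <- suppressWarnings(cone_partition_stats(dd, c(0, 0, 1), 30, 0.143))
  expect_equal(sort(c(st$inside, st$outside)), 1:100)
  expect_equal(st$resolution_inside, st$resolution_outside)

  expect_error(cone_partition_stats(dd, c(0, 0, 1), 0.1, 0.143), "inside")
})
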