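# Grid/Fourier foundation: MRC I/O, FFT conventions, masks, filters.

test_that("MRC round trip preserves data and pixel size", {
  set.seed(1)
  g <- voxel_grid(array(rnorm(32^3), c(32, 32, 32)), 1.05, name = "rt")
  path <- withr::local_tempfile(fileext = ".mrc")
  write_map(g, path)
  r1 <- read_map(path)
  expect_equal(r1$pixel_size, 1.05, tolerance = 1e-6)
  # data is stored as float32; a second round trip must be bitwise stable
  path2 <- withr::local_tempfile(fileext = ".mrc")
  write_map(r1, path2)
  r2 <- read_map(path2)
  expect_identical(r2$data, r1$data)
  expect_equal(r1$data, g$data, tolerance = 1e-6)

  g2 <- voxel_grid(array(seq_len(32^3) / 32^3, c(32, 32, 32)), 2.0)
  write_map(g2, path)
  expect_equal(read_map(path)$pixel_size, 2.0, tolerance = 1e-6)
})

test_that("read_map rejects missing files and non-cubic volumes", {
  expect_error(read_map(file.path(tempdir(), "nope.mrc")), "not found")
  # corrupt a valid file's nz header word to make it non-cubic
  path <- withr::local_tempfile(fileext = ".mrc")
  write_map(voxel_grid(array(0:1, c(32, 32, 32)), 1), path)
  bytes <- readBin(path, "raw", file.size(path))
  bytes[9:12] <- writeBin(16L, raw(), size = 4, endian = "little")
  writeBin(bytes, path)
  expect_error(read_map(path), "non-cubic")
})

test_that("fft3/ifft3 satisfy round trip, Parseval, and Friedel symmetry", {
  for (seed in 0:4) {
    set.seed(seed)
    g <- voxel_grid(array(rnorm(16^3), c(16, 16, 16)), 1)
    fv <- fft3(g)
    back <- ifft3(fv)
    expect_lt(sqrt(mean((back$data - g$data)^2)) / sqrt(mean(g$data^2)),
              1e-10)
    expect_lt(abs(sum(g$data^2) - sum(Mod(fv$data)^2) / 16^3) /
                sum(g$data^2), 1e-8)
    # Hermitian symmetry: F(-k) = conj(F(k)) in the DC-centered layout
    expect_lt(max(Mod(fv$data - Conj(centro_flip(fv$data)))) /
                max(Mod(fv$data)), 1e-6)
  }
})

test_that("fft3 of a centered delta has flat magnitude", {
  a <- array(0, c(16, 16, 16))
  a[9, 9, 9] <- 1                      # DC-centered convention: center voxel
  fv <- fft3(voxel_grid(a, 1))
  expect_lt(diff(range(Mod(fv$data))), 1e-12)
})

test_that("normalize_map gives mean 0 / sd 1, is idempotent, rejects constants", {
  set.seed(2)
  g <- voxel_grid(array(rnorm(16^3, mean = 5, sd = 2), c(16, 16, 16)), 1)
  nm <- normalize_map(g)
  expect_lt(abs(mean(nm$data)), 1e-8 * sd(g$data))
  expect_equal(sd(nm$data), 1, tolerance = 1e-8)
  again <- normalize_map(nm)
  expect_equal(again$data, nm$data, tolerance = 1e-10)
  expect_error(normalize_map(voxel_grid(array(3, c(8, 8, 8)), 1)),
               "zero variance")
})

test_that("lowpass_filter removes the stop band and preserves DC", {
  n <- 64
  ax <- seq_len(n)
  sinus <- voxel_grid(array(sin(2 * pi * ax / 4), c(n, n, n)), 1)  # 1/4 1/A
  out <- lowpass_filter(sinus, 6)
  expect_lt(sqrt(mean(out$data^2)), 1e-3 * sqrt(mean(sinus$data^2)))

  const <- voxel_grid(array(2.5, c(16, 16, 16)), 1)
  expect_equal(lowpass_filter(const, 6)$data, const$data, tolerance = 1e-10)

  expect_error(lowpass_filter(const, 1.5), "Nyquist")
})

test_that("lowpass_filter suppresses white-noise power beyond 1/resolution >= 1e6-fold", {
  set.seed(3)
  n <- 64
  g <- voxel_grid(array(rnorm(n^3), c(n, n, n)), 1)
  out <- lowpass_filter(g, 6)
  geo <- ardecon:::fourier_geometry(n)
  beyond <- geo$r / n > 1 / 6
  p_in <- sum(Mod(fft3(g)$data)[beyond]^2)
  p_out <- sum(Mod(fft3(out)$data)[beyond]^2)
  expect_lt(p_out, 1e-6 * p_in)
})

test_that("lowpass_filter never increases total power", {
  for (seed in 0:4) {
    set.seed(seed)
    g <- voxel_grid(array(rnorm(16^3), c(16, 16, 16)), 1)
    res <- runif(1, 2.5, 8)
    expect_lte(sum(lowpass_filter(g, res)$data^2), sum(g$data^2) + 1e-10)
  }
})

test_that("spherical_mask covers the density with a monotone soft edge", {
  n <- 64
  a <- array(0, c(n, n, n))
  a[33, 33, 33] <- 10
  m <- spherical_mask(voxel_grid(a, 1), threshold = 1, edge_width = 20)
  expect_s3_class(m, "mask_volume")
  expect_gte(min(m$data), 0)
  expect_lte(max(m$data), 1)
  expect_equal(m$data[33, 33, 33], 1)
  # monotone falloff along the +x ray through the center
  ray <- m$data[33:64, 33, 33]
  expect_true(all(diff(ray) <= 1e-12))

  # all voxels above threshold: mask is 1 throughout the inscribed sphere
  set.seed(6)
  full <- spherical_mask(voxel_grid(array(5, c(32, 32, 32)) +
                                      array(runif(32^3), c(32, 32, 32)),
                                    1), 1, 5)
  ctr <- (1 + 32) / 2
  ax <- seq_len(32)
  d <- sqrt(outer(outer((ax - ctr)^2, (ax - ctr)^2, `+`), (ax - ctr)^2, `+`))
  expect_true(all(full$data[d <= 16] == 1))

  expect_error(spherical_mask(voxel_grid(array(0, c(8, 8, 8)), 1), 1),
               "threshold")
})

test_that("apply_mask is a voxelwise product with shape checking", {
  set.seed(4)
  g <- voxel_grid(array(rnorm(8^3), c(8, 8, 8)), 1)
  one <- voxel_grid(array(1, c(8, 8, 8)), 1)
  zero <- voxel_grid(array(0, c(8, 8, 8)), 1)
  expect_identical(apply_mask(g, one)$data, g$data)
  expect_true(all(apply_mask(g, zero)$data == 0))
  half <- voxel_grid(array(rep(c(1, 0), each = 4 * 64), c(8, 8, 8)), 1)
  expect_true(all(apply_mask(g, half)$data[half$data == 0] == 0))
  big <- voxel_grid(array(1, c(16, 16, 16)), 1)
  expect_error(apply_mask(g, big), "shape")
})

test_that("fourier_amplitude is flat for a delta and centro-symmetric", {
  a <- array(0, c(16, 16, 16))
  a[9, 9, 9] <- 1
  amp <- fourier_amplitude(voxel_grid(a, 1))
  expect_lt(diff(range(amp$data)), 1e-12)

  set.seed(5)
  g <- voxel_grid(array(rnorm(16^3), c(16, 16, 16)), 1)
  amp <- fourier_amplitude(g)
  expect_lt(max(abs(amp$data - centro_flip(amp$data))) / max(amp$data), 1e-6)
})

test_that("cone-degraded map has empty Fourier cone at matched radii", {
  n <- 48
  truth <- make_phantom(n, 1, 25, seed = 1)
  cone <- missing_cone_mask(n, 30)
  ds <- degrade(truth, voxel_grid(1 - cone$data, 1), 0, seed = 1)
  amp <- as.vector(fourier_amplitude(ds$full)$data)
  geo <- ardecon:::fourier_geometry(n)
  band <- geo$shell >= 3L & geo$shell <= 22L
  inside <- as.vector(cone$data) > 0.5 & band
  outside <- as.vector(cone$data) < 0.5 & band
  expect_lt(mean(amp[inside]), 1e-6 * mean(amp[outside]))
})
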