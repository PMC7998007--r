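test_that("NIfTI write/read round trip preserves data and geometry exactly", {
  set.seed(11)
  vol <- image_volume(array(rnorm(4 * 5 * 6, 100, 20), c(4, 5, 6)),
                      spacing = c(0.8, 1.0, 1.25), origin = c(-10, 3.5, 22))
  path <- tempfile(fileext = ".nii.gz")
  write_volume(vol, path)
  back <- read_volume(path, "nifti")
  expect_identical(back$data, vol$data)
  expect_equal(back$spacing, vol$spacing, tolerance = 1e-12)
  expect_equal(back$origin, vol$origin, tolerance = 1e-9)
  expect_equal(back$direction, vol$direction, tolerance = 1e-9)
})

test_that("DICOM slices are sorted by position along the slice normal", {
  vol <- array(as.integer(matrix(1:48, 4)), c(4, 4, 3))
  dir <- tempfile()
  # files written in shuffled order with z positions 2, 0, 1
  write_test_dicom_series(dir, vol, z_positions = c(2, 0, 1))
  got <- read_volume(dir, "dicom_series")
  expect_equal(dim(got$data), c(4L, 4L, 3L))
  # ascending z: slice with position 0 first
  expect_equal(got$data[, , 1], vol[, , 2] + 0)
  expect_equal(got$data[, , 2], vol[, , 3] + 0)
  expect_equal(got$data[, , 3], vol[, , 1] + 0)
  expect_equal(got$spacing, c(1, 1, 1))
  expect_equal(got$origin, c(0, 0, 0))
})

test_that("DICOM series reading is invariant to input file order", {
  vol <- array(sample.int(500, 64, replace = TRUE), c(4, 4, 4))
  zpos <- c(0, 1.5, 3, 4.5)
  d1 <- tempfile(); d2 <- tempfile()
  write_test_dicom_series(d1, vol, zpos, file_order = 1:4)
  write_test_dicom_series(d2, vol, zpos, file_order = c(3, 1, 4, 2))
  a <- read_volume(d1, "dicom_series")
  b <- read_volume(d2, "dicom_series")
  expect_identical(a$data, b$data)
  expect_equal(a$spacing, b$spacing)
  expect_equal(a$spacing[3], 1.5)
})

test_that("heterogeneous or ill-spaced DICOM series are rejected", {
  vol <- array(1L, c(4, 4, 3))
  d <- tempfile()
  write_test_dicom_series(d, vol, z_positions = c(0, 1, 2))
  write_test_dicom(file.path(d, "im99.dcm"), vol[, , 1], c(0, 0, 3),
                   series_uid = "9.9.9")
  expect_error(read_volume(d, "dicom_series"), "format error")

  d2 <- tempfile()
  write_test_dicom_series(d2, vol, z_positions = c(0, 1, 2.5))
  expect_error(read_volume(d2, "dicom_series"), "geometry error")
})

test_that("header spacing is honoured for 1 mm isotropic acquisitions", {
  ph <- cached_phantom(seed = 42, noise_sigma = 5)
  expect_equal(ph$bundle$t1ce$spacing, c(1, 1, 1))
  path <- tempfile(fileext = ".nii.gz")
  write_volume(ph$bundle$t1ce, path)
  expect_equal(read_volume(path, "nifti")$spacing, c(1, 1, 1))
})

test_that("denoising a constant volume is the identity for both methods", {
  vol <- image_volume(array(7, c(6, 6, 6)))
  expect_equal(denoise_volume(vol, "median")$data, vol$data)
  expect_equal(denoise_volume(vol, "anisotropic_diffusion")$data, vol$data,
               tolerance = 1e-12)
})

test_that("median cross filter matches the hand-enumerated line case", {
  expect_equal(as.numeric(median_filter(array(c(0, 10, 0), c(3, 1, 1)))),
               c(0, 0, 0))
})

test_that("denoising reduces noise in a flat phantom region and preserves range", {
  ph <- cached_phantom(seed = 42, noise_sigma = 10)
  vol <- ph$bundle$t1ce
  flat <- array(FALSE, dim(vol$data))
  flat[1:12, 1:12, 1:12] <- TRUE   # pure background corner
  for (m in c("median", "anisotropic_diffusion")) {
    den <- denoise_volume(vol, m)
    expect_lt(sd(den$data[flat]), sd(vol$data[flat]))
    expect_gte(min(den$data), min(vol$data) - 1e-6)
    expect_lte(max(den$data), max(vol$data) + 1e-6)
  }
})

test_that("resampling to the same spacing is the identity", {
  vol <- image_volume(array(rnorm(60), c(3, 4, 5)), spacing = c(1, 1, 2))
  expect_identical(resample_volume(vol, c(1, 1, 2))$data, vol$data)
})

test_that("trilinear resampling of a linear ramp hits neighbour means", {
  n <- 7
  ramp <- array(rep(0:(n - 1), times = n * n), c(n, n, n))
  vol <- image_volume(ramp)
  half <- resample_volume(vol, c(0.5, 1, 1), "trilinear")
  # odd output samples sit midway between input voxels along x
  mids <- half$data[seq(2, 2 * n - 2, by = 2), 1, 1]
  expect_equal(mids, (0:(n - 2)) + 0.5)
})

test_that("nearest-neighbour resampling preserves a binary value set", {
  set.seed(3)
  mask <- array(rbinom(6 * 6 * 6, 1, 0.4), c(6, 6, 6))
  out <- resample_volume(image_volume(mask), c(0.7, 0.9, 1.3), "nearest")
  expect_true(all(out$data %in% c(0, 1)))
})

test_that("volumes with flipped/permuted axes are canonicalized on read", {
  set.seed(8)
  arr <- array(rnorm(4 * 5 * 6), c(4, 5, 6))
  vol <- image_volume(arr, spacing = c(1, 1.5, 2), origin = c(0, 0, 0),
                      direction = diag(c(-1, 1, 1)))
  path <- tempfile(fileext = ".nii.gz")
  write_volume(vol, path)
  back <- read_volume(path, "nifti")
  expect_equal(back$direction, diag(3))
  expect_equal(back$data, arr[4:1, , ], tolerance = 1e-12)
  expect_equal(back$origin, c(-3, 0, 0))
})
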