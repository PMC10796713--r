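# NIfTI and CSV round-trips, geometry checks, and contract violations.

test_that("volume write/read round-trips data, spacing and origin", {
  v <- Volume(array(rnorm(10 * 12 * 14), c(10, 12, 14)),
    spacing = c(0.35, 0.35, 0.35), origin = c(-1.2, 3.4, 0.7)
  )
  path <- file.path(withr::local_tempdir(), "vol.nii.gz")
  writeVolume(v, path)
  r <- readVolume(path)
  expect_equal(voxelData(r), voxelData(v), tolerance = 0)
  # header pixdim is a 32-bit float in NIfTI-1
  expect_equal(spacing(r), c(0.35, 0.35, 0.35), tolerance = 1e-6)
  expect_equal(origin(r), c(-1.2, 3.4, 0.7), tolerance = 1e-5)
})

test_that("float32 storage preserves values to datatype precision", {
  v <- Volume(array(runif(8^3, 0, 100), c(8, 8, 8)))
  path <- file.path(withr::local_tempdir(), "vol32.nii.gz")
  writeVolume(v, path, datatype = "float")
  r <- readVolume(path)
  expect_lt(max(abs(voxelData(r) - voxelData(v))), 100 * 2^-23)
})

test_that("non-3D images and missing files are rejected with diagnostics", {
  tmp <- withr::local_tempdir()
  expect_error(readVolume(file.path(tmp, "nope.nii.gz")), "not found")
  p2d <- file.path(tmp, "slice.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(matrix(rnorm(64), 8, 8)), p2d)
  expect_error(readVolume(p2d), "not a 3D volume")
  p4d <- file.path(tmp, "vec.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(rnorm(8^3 * 3), c(8, 8, 8, 3))), p4d)
  expect_error(readVolume(p4d), "not a 3D volume")
})

test_that("trailing singleton dimensions are tolerated", {
  tmp <- withr::local_tempdir()
  p <- file.path(tmp, "singleton.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(rnorm(8^3), c(8, 8, 8, 1))), p)
  expect_s4_class(readVolume(p), "Volume")
})

test_that("mask/volume geometry mismatch is an error, never a resample", {
  v <- Volume(array(0, c(10, 10, 10)), spacing = c(0.35, 0.35, 0.35))
  m1 <- LabelMask(array(TRUE, c(10, 10, 12)), spacing = c(0.35, 0.35, 0.35))
  expect_error(checkGeometry(v, m1), "shapes differ")
  m2 <- LabelMask(array(TRUE, c(10, 10, 10)), spacing = c(0.5, 0.5, 0.5))
  expect_error(checkGeometry(v, m2), "spacings differ")
  m3 <- LabelMask(array(TRUE, c(10, 10, 10)),
    spacing = c(0.35, 0.35, 0.35), origin = c(5, 0, 0)
  )
  expect_error(checkGeometry(v, m3), "origins differ")
})

test_that("mask round-trip preserves membership and checks its companion", {
  tmp <- withr::local_tempdir()
  m <- array(FALSE, c(9, 9, 9))
  m[3:6, 2:7, 4:8] <- TRUE
  mask <- LabelMask(m, spacing = c(0.35, 0.35, 0.35))
  p <- file.path(tmp, "mask.nii.gz")
  writeLabelMask(mask, p)
  back <- readLabelMask(p)
  expect_identical(voxelData(back), m)
  companion <- Volume(array(0, c(9, 9, 10)), spacing = c(0.35, 0.35, 0.35))
  expect_error(readLabelMask(p, reference = companion), "geometry mismatch")
})

test_that("displacement field round-trips through CSV to 1e-9 mm", {
  df <- data.frame(
    i = c(8L, 16L, 24L), j = c(8L, 8L, 8L), k = c(8L, 8L, 8L),
    ux_mm = c(0.123456789, -1.5, 0), uy_mm = c(0.5, 0.25, -0.125),
    uz_mm = c(1e-4, 2e-5, 0.75),
    correlation = c(0.99, 0.98, 0.6), valid = c(TRUE, TRUE, FALSE)
  )
  fld <- makeField(df, gridStep = 8L)
  prefix <- file.path(withr::local_tempdir(), "field")
  writeDisplacementField(fld, prefix)
  back <- readDisplacementField(prefix, spacing = spacing(fld))
  expect_equal(back$ux_mm, df$ux_mm, tolerance = 1e-9)
  expect_equal(back$uy_mm, df$uy_mm, tolerance = 1e-9)
  expect_equal(back$uz_mm, df$uz_mm, tolerance = 1e-9)
  expect_identical(back$valid, df$valid)
  expect_equal(back$ux_vox, df$ux_mm / 0.35, tolerance = 1e-9)
})

test_that("invalid nodes become NaN in the NIfTI field image", {
  df <- data.frame(
    i = c(0L, 8L), j = c(0L, 0L), k = c(0L, 0L),
    ux_mm = c(0, 0.5), uy_mm = c(0, 0), uz_mm = c(0, 0),
    correlation = c(0.99, 0.5), valid = c(TRUE, FALSE)
  )
  fld <- makeField(df, gridStep = 8L)
  prefix <- file.path(withr::local_tempdir(), "field")
  writeDisplacementField(fld, prefix)
  img <- RNifti::readNifti(paste0(prefix, ".nii.gz"))
  expect_equal(dim(img), c(2L, 1L, 1L, 3L))
  expect_false(is.nan(img[1, 1, 1, 1]))
  expect_equal(img[1, 1, 1, 1], 0) # all-zero valid node stores zero
  expect_true(all(is.nan(img[2, 1, 1, ]))) # invalid node stored as NaN
})
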