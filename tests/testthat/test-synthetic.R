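# Phantom synthesis: texture statistics, warping exactness, and the
# knee-scene ground-truth invariants.

test_that("texture generation is bitwise reproducible and respects range", {
  spec <- textureSpec(shape = c(24, 24, 24), noiseSd = 0, seed = 11)
  v1 <- generateTextureVolume(spec)
  v2 <- generateTextureVolume(spec)
  expect_identical(voxelData(v1), voxelData(v2))
  expect_gte(min(voxelData(v1)), 0)
  expect_lte(max(voxelData(v1)), 100)
  v3 <- generateTextureVolume(textureSpec(
    shape = c(24, 24, 24), noiseSd = 0, seed = 12
  ))
  expect_false(identical(voxelData(v1), voxelData(v3)))
})

test_that("texture spec rejects invalid parameters", {
  expect_error(textureSpec(shape = c(10, 48, 48), correlationLength = 2),
    "shape too small")
  expect_error(textureSpec(correlationLength = 0.2), ">= 0.5")
  expect_error(textureSpec(intensityRange = c(5, 5)), "lo < hi")
  expect_error(textureSpec(noiseSd = -1), ">= 0")
})

test_that("texture autocorrelation width matches the requested length", {
  # FFT oracle: empirical autocorrelation of the generated volume,
  # compared with the analytic Gaussian-kernel autocorrelation
  # exp(-r^2 / (4 sigma^2)), whose half-width at half-maximum is
  # 2 sigma sqrt(ln 2).
  sigma <- 2
  spec <- textureSpec(shape = c(64, 64, 64), correlationLength = sigma,
    noiseSd = 0, seed = 21)
  a <- voxelData(generateTextureVolume(spec))
  a <- a - mean(a)
  f <- fft(a)
  ac <- Re(fft(f * Conj(f), inverse = TRUE))
  ac <- ac / ac[1, 1, 1]
  prof <- ac[1:20, 1, 1] # autocorrelation along x at lag 0..19
  # empirical half-width: first lag where autocorrelation drops below 1/2
  below <- which(prof < 0.5)[1]
  hwhm <- (below - 2) + (prof[below - 1] - 0.5) / (prof[below - 1] - prof[below])
  expect_lt(abs(hwhm - 2 * sigma * sqrt(log(2))), 0.3 * 2 * sigma * sqrt(log(2)))
})

test_that("identity warp returns the input on the interior", {
  v <- smallTexture(c(20, 20, 20), seed = 3)
  w <- warpVolume(v, translationWarp(c(0, 0, 0)))
  inner <- voxelData(w$volume)[3:18, 3:18, 3:18]
  expect_equal(inner, voxelData(v)[3:18, 3:18, 3:18], tolerance = 1e-12)
  expect_true(all(w$inDomain[3:18, 3:18, 3:18]))
})

test_that("integer translations shift voxels exactly", {
  v <- smallTexture(c(20, 20, 20), seed = 4)
  w <- warpVolume(v, translationWarp(c(2, 0, -1)))
  a <- voxelData(w$volume)
  b <- voxelData(v)
  expect_equal(a[6:16, 6:16, 6:16], b[4:14, 6:16, 7:17], tolerance = 0)
})

test_that("fractional warps of cubic polynomial volumes are exact", {
  d <- c(16, 16, 16)
  g <- expand.grid(x = 0:15, y = 0:15, z = 0:15)
  poly <- function(x, y, z) x^3 + 2 * y^2 - z
  v <- Volume(array(poly(g$x, g$y, g$z), d))
  tau <- c(0.3, -0.4, 0.1)
  w <- warpVolume(v, translationWarp(tau))
  idx <- as.matrix(expand.grid(4:11, 4:11, 4:11))
  got <- voxelData(w$volume)[idx + 1L]
  want <- poly(idx[, 1] - tau[1], idx[, 2] - tau[2], idx[, 3] - tau[3])
  expect_lt(max(abs(got - want)), 1e-9)
})

test_that("warping with a model then its inverse restores the interior", {
  v <- smoothTrigVolume(c(32, 32, 32))
  model <- rigidWarp(
    rotation = c(0, 0, 2), translation = c(0.7, -0.4, 0.3),
    center = c(15.5, 15.5, 15.5)
  )
  fwd <- warpVolume(v, model)$volume
  inv <- rigidWarp(
    rotation = mridvc:::.eulerFromMatrixDeg(
      t(mridvc:::.rotationMatrixDeg(c(0, 0, 2)))
    ),
    translation = -as.numeric(
      t(mridvc:::.rotationMatrixDeg(c(0, 0, 2))) %*% c(0.7, -0.4, 0.3)
    ),
    center = c(15.5, 15.5, 15.5)
  )
  back <- warpVolume(fwd, inv)$volume
  rng <- diff(range(voxelData(v)))
  inner <- 7:26
  expect_lt(
    max(abs(
      voxelData(back)[inner, inner, inner] - voxelData(v)[inner, inner, inner]
    )),
    1e-6 * rng # two tricubic resamplings of a smooth volume
  )
})

test_that("gaussian bump displacement is bounded by its peak", {
  m <- gaussianBumpWarp(center = c(10, 10, 10), sigma = 4, peak = c(3, -2, 1))
  set.seed(1)
  X <- matrix(runif(300, 0, 20), ncol = 3)
  u <- warpDisplacement(m, X)
  expect_true(all(abs(u[, 1]) <= 3 + 1e-12))
  expect_true(all(abs(u[, 2]) <= 2 + 1e-12))
  expect_true(all(abs(u[, 3]) <= 1 + 1e-12))
  expect_equal(
    as.numeric(warpDisplacement(m, c(10, 10, 10))), c(3, -2, 1)
  )
})

test_that("phantom scene enforces its ground-truth invariants", {
  spec <- textureSpec(shape = c(64, 64, 64), seed = 31)
  tauMm <- c(-1.568, 0, 0) # injured-knee extrusion scale at 1500 N
  tauVox <- tauMm / 0.35
  scene <- generateKneePhantom(spec, translationWarp(tauVox))
  menis <- voxelData(scene@meniscusMask)
  bone <- voxelData(scene@boneMask)
  expect_false(any(menis & bone))
  # truth is exactly the model inside the meniscus mask
  nodesM <- which(menis, arr.ind = TRUE) - 1L
  uM <- truthField(scene, nodesM[seq(1, nrow(nodesM), by = 97), , drop = FALSE])
  expect_true(all(abs(sweep(uM, 2, tauVox)) < 1e-12))
  # ground-truth mean X displacement over the mask, in mm
  expect_equal(mean(uM[, 1]) * 0.35, -1.568, tolerance = 1e-9)
  # truth is exactly zero inside the bone mask
  nodesB <- which(bone, arr.ind = TRUE) - 1L
  uB <- truthField(scene, nodesB[seq(1, nrow(nodesB), by = 201), , drop = FALSE])
  expect_true(all(uB == 0))
})

test_that("phantom generation is reproducible and noise realizations differ", {
  spec <- textureSpec(shape = c(64, 64, 64), seed = 32)
  s1 <- generateKneePhantom(spec, translationWarp(c(0, 0, 0)))
  s2 <- generateKneePhantom(spec, translationWarp(c(0, 0, 0)))
  expect_identical(voxelData(s1@reference), voxelData(s2@reference))
  expect_identical(voxelData(s1@deformed), voxelData(s2@deformed))
  # zero model + identity perturbation = two noisy images of one state
  # (interior only: the resampling rim of the deformed volume is filled)
  inner <- 3:62
  diffs <- voxelData(s1@reference)[inner, inner, inner] -
    voxelData(s1@deformed)[inner, inner, inner]
  expect_gt(sd(diffs), 0.5 * sqrt(2) * spec$noiseSd)
  expect_lt(sd(diffs), 2 * sqrt(2) * spec$noiseSd)
})

test_that("overlapping meniscus and bone regions are rejected", {
  spec <- textureSpec(shape = c(64, 64, 64), seed = 33)
  expect_error(
    generateKneePhantom(spec, translationWarp(c(0, 0, 0)),
      geometry = list(boneHi = c(0.8, 0.8, 0.8))
    ),
    "overlapping masks"
  )
})
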