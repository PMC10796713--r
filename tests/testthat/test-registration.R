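# Rigid transform algebra and bone-referenced registration recovery.

makeBoneScene <- function(seed, rotation, translationVox, d = c(64, 64, 64)) {
  spec <- textureSpec(shape = d, noiseSd = 1, seed = seed)
  ref <- generateTextureVolume(spec, noiseSeed = seed + 100L)
  ctr <- (d - 1) / 2
  B <- rigidWarp(rotation = rotation, translation = translationVox, center = ctr)
  mov <- warpVolume(generateTextureVolume(spec, noiseSeed = seed + 200L), B)$volume
  m <- array(FALSE, d)
  m[17:48, 17:48, 17:48] <- TRUE
  list(
    ref = ref, mov = mov,
    mask = LabelMask(m, spacing = spacing(ref)),
    truth = rigidTransform(rotation, translationVox * spacing(ref),
      center = ctr * spacing(ref)
    )
  )
}

meanResidualVox <- function(got, want, mask, sp) {
  pts <- (which(voxelData(mask), arr.ind = TRUE) - 1)
  pmm <- sweep(pts, 2, sp, "*")
  res <- transformPoints(got, pmm) - transformPoints(want, pmm)
  mean(sqrt(rowSums(res^2))) / sp[1]
}

test_that("rigid transform algebra: inverse and composition", {
  t1 <- rigidTransform(c(3, -2, 5), c(1.2, -0.7, 0.4), center = c(5, 5, 5))
  ti <- rigidInverse(t1)
  comp <- rigidCompose(ti, t1)
  set.seed(1)
  pts <- matrix(runif(60, -10, 10), ncol = 3)
  expect_lt(max(abs(transformPoints(comp, pts) - pts)), 1e-9)
  expect_lt(max(abs(comp@rotation)), 1e-9)
  expect_lt(max(abs(comp@translation)), 1e-9)
  expect_error(
    rigidCompose(t1, rigidTransform(center = c(0, 0, 0))),
    "share one rotation centre"
  )
})

test_that("applyRigid is exact for identity and integer shifts", {
  v <- smallTexture(c(24, 24, 24), seed = 21)
  idm <- rigidTransform(center = (dim(voxelData(v)) - 1) / 2 * spacing(v))
  out <- applyRigid(v, idm)
  expect_equal(
    voxelData(out$volume)[3:22, 3:22, 3:22],
    voxelData(v)[3:22, 3:22, 3:22],
    tolerance = 1e-12
  )
  # pure integer-voxel translation resamples exactly on grid nodes (to
  # the round-off of the mm coordinate conversion)
  tr <- rigidTransform(translation = c(2, 0, -1) * spacing(v))
  sh <- voxelData(applyRigid(v, tr)$volume)
  expect_equal(sh[5:18, 5:18, 5:18], voxelData(v)[7:20, 5:18, 4:17],
    tolerance = 1e-9
  )
})

test_that("applyRigid then its inverse restores the interior", {
  v <- smoothTrigVolume(c(32, 32, 32))
  t1 <- rigidTransform(c(1.5, -1, 2), c(0.3, -0.2, 0.15),
    center = (dim(voxelData(v)) - 1) / 2 * spacing(v)
  )
  fwd <- applyRigid(v, t1)$volume
  back <- applyRigid(fwd, rigidInverse(t1))$volume
  rng <- diff(range(voxelData(v)))
  inner <- 7:26
  expect_lt(
    max(abs(
      voxelData(back)[inner, inner, inner] - voxelData(v)[inner, inner, inner]
    )),
    1e-6 * rng # two tricubic resamplings of a smooth volume
  )
})

test_that("registering a volume against itself returns the identity", {
  sc <- makeBoneScene(31, c(0, 0, 0), c(0, 0, 0))
  tr <- registerRigid(sc$ref, sc$ref, sc$mask)
  expect_gt(tr@correlation, 0.999)
  expect_true(tr@metricOk)
  resid <- meanResidualVox(
    tr, rigidTransform(center = tr@center), sc$mask, spacing(sc$ref)
  )
  expect_lt(resid, 0.02)
})

test_that("a known rigid perturbation is recovered below 0.1 voxel", {
  sc <- makeBoneScene(32, c(0, 0, 1.2), c(0.7, -0.3, 0.2))
  tr <- registerRigid(sc$ref, sc$mov, sc$mask)
  expect_true(tr@metricOk)
  expect_lt(meanResidualVox(tr, sc$truth, sc$mask, spacing(sc$ref)), 0.1)
})

test_that("recovery holds across perturbations up to 3 degrees / 3 voxels", {
  cases <- list(
    list(rot = c(2.5, -1.5, 3), tr = c(2, -3, 1)),
    list(rot = c(-3, 0.5, -2), tr = c(-1.5, 2.5, -3))
  )
  for (cs in cases) {
    sc <- makeBoneScene(40 + round(sum(abs(cs$rot))), cs$rot, cs$tr)
    tr <- registerRigid(sc$ref, sc$mov, sc$mask)
    expect_lt(meanResidualVox(tr, sc$truth, sc$mask, spacing(sc$ref)), 0.1)
  }
})

test_that("registration is invariant to affine intensity rescaling", {
  sc <- makeBoneScene(33, c(0, 0, 0.8), c(0.5, 0.2, -0.4))
  t1 <- registerRigid(sc$ref, sc$mov, sc$mask)
  mov2 <- Volume(2 * voxelData(sc$mov) + 5,
    spacing = spacing(sc$mov), origin = origin(sc$mov)
  )
  t2 <- registerRigid(sc$ref, mov2, sc$mask)
  expect_lt(meanResidualVox(t1, t2, sc$mask, spacing(sc$ref)), 0.02)
})

test_that("an empty bone mask is rejected and low metric is flagged", {
  v <- smallTexture(c(24, 24, 24), seed = 23)
  empty <- LabelMask(array(FALSE, c(24, 24, 24)), spacing = spacing(v))
  expect_error(registerRigid(v, v, empty), "empty")
  # structurally unrelated volumes cannot reach the metric floor
  other <- smallTexture(c(24, 24, 24), seed = 99)
  m <- array(FALSE, c(24, 24, 24))
  m[7:18, 7:18, 7:18] <- TRUE
  expect_warning(
    tr <- registerRigid(v, other, LabelMask(m, spacing = spacing(v)),
      metricFloor = 0.9
    ),
    "below floor"
  )
  expect_false(tr@metricOk)
})

test_that("rigid transforms round-trip through JSON", {
  t1 <- rigidTransform(c(1.25, -0.5, 2), c(0.35, -0.7, 0.105),
    center = c(11.025, 11.025, 11.025)
  )
  t1@correlation <- 0.987
  p <- file.path(withr::local_tempdir(), "T.json")
  writeRigidTransform(t1, p)
  t2 <- readRigidTransform(p)
  expect_equal(t2@rotation, t1@rotation, tolerance = 1e-12)
  expect_equal(t2@translation, t1@translation, tolerance = 1e-12)
  expect_equal(t2@center, t1@center, tolerance = 1e-12)
  expect_equal(t2@correlation, 0.987)
})
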