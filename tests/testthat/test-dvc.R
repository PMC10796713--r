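# Correlation engine: similarity criterion, interpolation exactness,
# integer search against an independent brute-force oracle, subvoxel
# refinement against a dense-sampling oracle, and the engine invariances.

test_that("zncc satisfies its algebraic identities", {
  set.seed(2)
  a <- array(rnorm(5^3), c(5, 5, 5))
  expect_equal(zncc(a, a), 1)
  expect_equal(zncc(a, 2 * a + 5), 1) # affine intensity invariance
  expect_equal(zncc(a, -a), -1)
  expect_error(zncc(a, array(0, c(5, 5, 5))), "textureless")
  expect_error(zncc(a, array(rnorm(27), c(3, 3, 3))), "identical shape")
})

test_that("tricubic interpolation is exact at nodes and on cubics", {
  d <- c(12, 12, 12)
  g <- expand.grid(x = 0:11, y = 0:11, z = 0:11)
  lin <- array(3 * g$x - g$y + 0.5 * g$z + 7, d)
  cub <- array(g$x^3, d)
  set.seed(3)
  pts <- matrix(runif(150, 1, 9.99), ncol = 3)
  # grid nodes are reproduced exactly
  nodes <- matrix(c(3, 4, 5, 1, 10, 10), ncol = 3, byrow = TRUE)
  expect_equal(
    tricubicInterpolate(Volume(lin), nodes),
    lin[nodes + 1L],
    tolerance = 1e-12
  )
  expect_lt(
    max(abs(
      tricubicInterpolate(Volume(lin), pts) -
        (3 * pts[, 1] - pts[, 2] + 0.5 * pts[, 3] + 7)
    )), 1e-10
  )
  expect_lt(
    max(abs(tricubicInterpolate(Volume(cub), pts) - pts[, 1]^3)), 1e-9
  )
  expect_error(
    tricubicInterpolate(Volume(lin), matrix(c(0.5, 5, 5), ncol = 3)),
    "outside the tricubic support"
  )
})

test_that("integer search equals the exhaustive brute-force argmax", {
  set.seed(7)
  d <- c(26, 26, 26)
  for (rep in 1:2) {
    ref <- Volume(array(rnorm(prod(d)), d))
    def <- Volume(array(rnorm(prod(d)), d))
    for (q in 1:15) {
      node <- sample(8:17, 3, replace = TRUE)
      h <- sample(3:4, 1)
      radius <- sample(2:4, 1)
      got <- integerSearch(ref, def, node, dvcConfig(
        subsetHalfWidth = h, searchRadius = radius
      ))
      want <- bruteForceSearch(ref, def, node, h, radius)
      expect_identical(got$offset, want$offset)
      expect_equal(got$correlation, want$correlation, tolerance = 1e-9)
    }
  }
})

test_that("integer search recovers known shifts and flags lost matches", {
  ref <- smallTexture(c(40, 40, 40), seed = 8)
  def <- warpVolume(ref, translationWarp(c(3, -2, 1)))$volume
  cfg <- dvcConfig(subsetHalfWidth = 5, searchRadius = 5)
  got <- integerSearch(ref, def, c(20, 20, 20), cfg)
  expect_identical(got$offset, c(3L, -2L, 1L))
  expect_gt(got$correlation, 0.999)
  expect_identical(
    integerSearch(ref, ref, c(20, 20, 20), cfg)$offset, c(0L, 0L, 0L)
  )
  # a shift beyond the search radius cannot be matched: the returned
  # offset is still the in-ball maximum (oracle agrees) but correlates
  # poorly against the true matched value
  far <- warpVolume(ref, translationWarp(c(7, 0, 0)))$volume
  lost <- integerSearch(ref, far, c(20, 20, 20), cfg)
  want <- bruteForceSearch(ref, far, c(20, 20, 20), 5, 5)
  expect_identical(lost$offset, want$offset)
  expect_lt(lost$correlation, got$correlation - 0.05)
})

test_that("textureless subsets are an error for single-node search", {
  flat <- Volume(array(1, c(24, 24, 24)))
  expect_error(
    integerSearch(flat, flat, c(12, 12, 12), dvcConfig(
      subsetHalfWidth = 3, searchRadius = 2
    )),
    "textureless"
  )
  v <- smallTexture(c(24, 24, 24))
  expect_error(
    integerSearch(v, v, c(2, 12, 12), dvcConfig(
      subsetHalfWidth = 3, searchRadius = 2
    )),
    "exceeds the volume bounds"
  )
})

test_that("subvoxel refinement recovers imposed subvoxel translations", {
  ref <- smallTexture(c(40, 40, 40), seed = 9)
  cfg <- dvcConfig(subsetHalfWidth = 5, searchRadius = 2, prefilterSigma = 0)
  # null case: start at zero on identical volumes
  r0 <- subvoxelRefine(ref, ref, c(20, 20, 20), c(0, 0, 0), cfg)
  expect_true(r0$converged)
  expect_lt(max(abs(r0$u)), cfg@tol)
  expect_gt(r0$correlation, 1 - 1e-9)
  # 0.30 voxel imposed along X, recovered within the 0.05-voxel
  # instrument uncertainty
  def <- warpVolume(ref, translationWarp(c(0.3, 0, 0)))$volume
  r <- subvoxelRefine(ref, def, c(20, 20, 20), c(0, 0, 0), cfg)
  expect_true(r$converged)
  expect_lt(max(abs(r$u - c(0.3, 0, 0))), 0.05)
})

test_that("refinement agrees with a dense-sampling oracle of the objective", {
  ref <- smallTexture(c(40, 40, 40), seed = 10)
  def <- warpVolume(ref, translationWarp(c(0.37, -0.21, 0.12)))$volume
  cfg <- dvcConfig(subsetHalfWidth = 6, searchRadius = 2, prefilterSigma = 0)
  node <- c(20, 20, 20)
  h <- 6
  r <- subvoxelRefine(ref, def, node, c(0, 0, 0), cfg)
  offs <- as.matrix(expand.grid(-h:h, -h:h, -h:h))
  sub <- voxelData(ref)[
    (node[1] - h):(node[1] + h) + 1L, (node[2] - h):(node[2] + h) + 1L,
    (node[3] - h):(node[3] + h) + 1L
  ]
  objective <- function(u) {
    g <- tricubicInterpolate(def, sweep(offs, 2, node + u, "+"))
    zncc(sub, array(g, dim(sub)))
  }
  # 1D sections on a 0.001-voxel grid through the reported optimum
  for (ax in 1:3) {
    ts <- seq(-0.05, 0.05, by = 0.001)
    vals <- vapply(ts, function(t) {
      u <- r$u
      u[ax] <- u[ax] + t
      objective(u)
    }, numeric(1))
    tOpt <- ts[which.max(vals)]
    expect_lt(abs(tOpt), 0.01)
  }
})

test_that("correlateVolumes recovers uniform translations at every node", {
  ref <- smallTexture(c(48, 48, 48), seed = 12)
  tau <- c(0.4, -0.6, 0.2)
  def <- warpVolume(ref, translationWarp(tau))$volume
  cfg <- dvcConfig(subsetHalfWidth = 5, gridStep = 8, searchRadius = 2)
  fld <- correlateVolumes(ref, def, fullRoi(ref), cfg)
  v <- records(fld, validOnly = TRUE)
  expect_gt(nrow(v), 20)
  err <- cbind(v$ux_vox - tau[1], v$uy_vox - tau[2], v$uz_vox - tau[3])
  expect_lt(max(abs(err)), 0.05)
  expect_lt(mean(sqrt(rowSums(err^2))), 0.02)
  # u_mm consistency with spacing
  expect_equal(v$ux_mm, v$ux_vox * spacing(fld)[1], tolerance = 1e-12)
})

test_that("the null pair yields zero displacement at every valid node", {
  ref <- smallTexture(c(40, 40, 40), seed = 13)
  cfg <- dvcConfig(subsetHalfWidth = 5, gridStep = 8, searchRadius = 2)
  fld <- correlateVolumes(ref, ref, fullRoi(ref), cfg)
  v <- records(fld, validOnly = TRUE)
  expect_gt(nrow(v), 0)
  expect_lt(max(abs(cbind(v$ux_vox, v$uy_vox, v$uz_vox))), cfg@tol)
})

test_that("the pipeline is translation-equivariant and intensity-invariant", {
  ref <- smallTexture(c(48, 48, 48), seed = 14)
  def <- warpVolume(ref, translationWarp(c(0.3, 0.2, -0.4)))$volume
  cfg <- dvcConfig(subsetHalfWidth = 5, gridStep = 8, searchRadius = 2)
  roi <- boxRoi(ref, c(16, 16, 16), c(31, 31, 31))
  f1 <- correlateVolumes(ref, def, roi, cfg)
  # shift both volumes (and the ROI) by the same integer vector: crop two
  # 40^3 windows of the same scene, one displaced by sh
  sh <- c(4L, 0L, -4L)
  sub <- function(arr, off) {
    arr[(1:40) + off[1], (1:40) + off[2], (1:40) + off[3]]
  }
  refS <- Volume(sub(voxelData(ref), c(4, 4, 4)))
  defS <- Volume(sub(voxelData(def), c(4, 4, 4)))
  refT <- Volume(sub(voxelData(ref), c(4, 4, 4) + sh))
  defT <- Volume(sub(voxelData(def), c(4, 4, 4) + sh))
  roiS <- boxRoi(refS, c(14, 14, 14), c(25, 25, 25))
  roiT <- boxRoi(refT, c(14, 14, 14) - sh, c(25, 25, 25) - sh)
  fS <- correlateVolumes(refS, defS, roiS, cfg)
  fT <- correlateVolumes(refT, defT, roiT, cfg)
  vS <- records(fS, validOnly = TRUE)
  vT <- records(fT, validOnly = TRUE)
  # match nodes at corresponding physical positions
  vT$i <- vT$i + sh[1]
  vT$j <- vT$j + sh[2]
  vT$k <- vT$k + sh[3]
  mrg <- merge(vS, vT, by = c("i", "j", "k"), suffixes = c("_s", "_t"))
  expect_gt(nrow(mrg), 0)
  expect_equal(mrg$ux_vox_s, mrg$ux_vox_t, tolerance = 1e-10)
  expect_equal(mrg$uy_vox_s, mrg$uy_vox_t, tolerance = 1e-10)
  expect_equal(mrg$uz_vox_s, mrg$uz_vox_t, tolerance = 1e-10)
  # affine intensity rescaling leaves the field unchanged
  def2 <- Volume(2 * voxelData(def) + 5, spacing = spacing(def))
  f2 <- correlateVolumes(ref, def2, roi, cfg)
  v1 <- records(f1)
  v2 <- records(f2)
  expect_equal(v1$ux_vox, v2$ux_vox, tolerance = 1e-8)
  expect_equal(v1$correlation, v2$correlation, tolerance = 1e-8)
})

test_that("an undersized ROI is rejected with a diagnostic", {
  ref <- smallTexture(c(24, 24, 24), seed = 15)
  roi <- boxRoi(ref, c(0, 0, 0), c(3, 3, 3)) # hugs the boundary
  expect_error(
    correlateVolumes(ref, ref, roi, dvcConfig(
      subsetHalfWidth = 5, searchRadius = 3
    )),
    "ROI too small"
  )
  empty <- LabelMask(array(FALSE, c(24, 24, 24)), spacing = spacing(ref))
  expect_error(correlateVolumes(ref, ref, empty, dvcConfig()), "empty")
})

test_that("measurement error shrinks as the subset grows", {
  # statistically over 20 random textures at fixed noise
  set.seed(16)
  seeds <- sample.int(10000, 20)
  tau <- c(0.3, 0, 0)
  meanAbsErr <- sapply(c(3L, 5L, 8L), function(h) {
    errs <- unlist(lapply(seeds, function(s) {
      spec <- textureSpec(shape = c(40, 40, 40), seed = s)
      base <- generateTextureVolume(
        textureSpec(shape = c(40, 40, 40), noiseSd = 0, seed = s)
      )
      set.seed(s + 5000L)
      n1 <- array(rnorm(40^3, sd = spec$noiseSd), c(40, 40, 40))
      n2 <- array(rnorm(40^3, sd = spec$noiseSd), c(40, 40, 40))
      ref <- Volume(voxelData(base) + n1)
      def <- Volume(
        voxelData(warpVolume(base, translationWarp(tau))$volume) + n2
      )
      cfg <- dvcConfig(
        subsetHalfWidth = h, gridStep = 10, searchRadius = 2
      )
      v <- records(
        correlateVolumes(ref, def, fullRoi(ref), cfg),
        validOnly = TRUE
      )
      abs(v$ux_vox - tau[1])
    }))
    mean(errs)
  })
  expect_true(all(diff(meanAbsErr) < 0))
})

test_that("shape order 1 recovers a uniform subset stretch", {
  spec <- textureSpec(shape = c(64, 64, 64), noiseSd = 0, seed = 4)
  ref <- generateTextureVolume(spec)
  A <- diag(rep(1.02, 3))
  ctr <- rep(31.5, 3)
  model <- affineWarp(A, translation = -(as.numeric(A %*% ctr) - ctr))
  def <- warpVolume(ref, model)$volume
  nodes <- as.matrix(expand.grid(c(24, 32, 40), c(24, 32, 40), c(24, 32, 40)))
  truth <- warpDisplacement(model, nodes)
  errAt <- function(shapeOrder) {
    cfg <- dvcConfig(
      subsetHalfWidth = 8, searchRadius = 2,
      shapeOrder = shapeOrder, prefilterSigma = 0
    )
    sapply(seq_len(nrow(nodes)), function(q) {
      r <- subvoxelRefine(ref, def, nodes[q, ], round(truth[q, ]), cfg)
      max(abs(r$u - truth[q, ]))
    })
  }
  e0 <- errAt(0L)
  e1 <- errAt(1L)
  expect_lt(max(e1), 0.05)
  expect_gt(mean(e0), 3 * mean(e1)) # order 0 shows measurable bias
})
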