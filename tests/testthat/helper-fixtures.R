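# Shared fixtures: all synthetic, generated in code at test time.

# small noiseless smooth texture for engine unit tests
smallTexture <- function(shape = c(32, 32, 32), seed = 5, noiseSd = 0,
                         correlationLength = 2) {
  generateTextureVolume(textureSpec(
    shape = shape, correlationLength = correlationLength,
    noiseSd = noiseSd, seed = seed
  ))
}

# very smooth analytic volume (slow trigonometric variation) for
# resampling round-trip bounds that probe interpolation error alone
smoothTrigVolume <- function(d = c(32, 32, 32), spacing = c(0.35, 0.35, 0.35)) {
  g <- expand.grid(x = 0:(d[1] - 1), y = 0:(d[2] - 1), z = 0:(d[3] - 1))
  arr <- array(
    sin(2 * pi * g$x / 128) + sin(2 * pi * g$y / 128 + 0.7) +
      sin(2 * pi * g$z / 128 + 1.3),
    d
  )
  Volume(arr, spacing = spacing)
}

# full-volume ROI mask matching a volume's grid
fullRoi <- function(vol) {
  LabelMask(array(TRUE, dim(voxelData(vol))),
    spacing = spacing(vol), origin = origin(vol)
  )
}

# central-box ROI (0-based inclusive bounds)
boxRoi <- function(vol, lo, hi) {
  d <- dim(voxelData(vol))
  m <- array(FALSE, d)
  m[(lo[1]:hi[1]) + 1L, (lo[2]:hi[2]) + 1L, (lo[3]:hi[3]) + 1L] <- TRUE
  LabelMask(m, spacing = spacing(vol), origin = origin(vol))
}

# independent brute-force ZNCC argmax over the search ball (R oracle)
bruteForceSearch <- function(ref, def, node, h, radius) {
  ra <- voxelData(ref)
  da <- voxelData(def)
  sub <- ra[
    (node[1] - h):(node[1] + h) + 1L, (node[2] - h):(node[2] + h) + 1L,
    (node[3] - h):(node[3] + h) + 1L
  ]
  best <- -2
  bo <- c(0L, 0L, 0L)
  bn2 <- Inf
  for (ok in -radius:radius) {
    for (oj in -radius:radius) {
      for (oi in -radius:radius) {
        n2 <- oi^2 + oj^2 + ok^2
        if (n2 > radius^2) next
        g <- da[
          (node[1] + oi - h):(node[1] + oi + h) + 1L,
          (node[2] + oj - h):(node[2] + oj + h) + 1L,
          (node[3] + ok - h):(node[3] + ok + h) + 1L
        ]
        cz <- zncc(sub, g)
        take <- cz > best ||
          (cz == best && (n2 < bn2 ||
            (n2 == bn2 && (oi < bo[1] || (oi == bo[1] && (oj < bo[2] ||
              (oj == bo[2] && ok < bo[3])))))))
        if (take) {
          best <- cz
          bo <- c(oi, oj, ok)
          bn2 <- n2
        }
      }
    }
  }
  list(offset = bo, correlation = best)
}

# hand-built displacement field on a tiny grid from explicit records
makeField <- function(df, spacing = c(0.35, 0.35, 0.35), gridStep = 1L) {
  full <- data.frame(
    i = df$i, j = df$j, k = df$k,
    ux_vox = df$ux_mm / spacing[1], uy_vox = df$uy_mm / spacing[2],
    uz_vox = df$uz_mm / spacing[3],
    ux_mm = df$ux_mm, uy_mm = df$uy_mm, uz_mm = df$uz_mm,
    correlation = if (is.null(df$correlation)) rep(0.99, nrow(df)) else df$correlation,
    iterations = 1L,
    converged = TRUE,
    valid = if (is.null(df$valid)) rep(TRUE, nrow(df)) else df$valid
  )
  mridvc:::displacementField(
    full,
    gridDims = c(
      diff(range(df$i)) %/% gridStep + 1L, diff(range(df$j)) %/% gridStep + 1L,
      diff(range(df$k)) %/% gridStep + 1L
    ),
    gridOrigin = c(min(df$i), min(df$j), min(df$k)),
    gridStep = gridStep, spacing = spacing, origin = c(0, 0, 0)
  )
}
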