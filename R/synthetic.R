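# Synthetic MRI-like phantoms with known ground-truth displacement
# fields: smooth Gaussian-correlated texture, warped acquisitions, and a
# knee-like scene (stationary bone block + mobile meniscal wedge).

#' Specification of an MRI-like random texture
#'
#' The texture emulates the grey-level structure a high-resolution DESS
#' knee acquisition offers to subset matching: white noise low-pass
#' filtered with a Gaussian kernel of sigma `correlationLength` voxels,
#' rescaled to `intensityRange`, plus independent additive Gaussian
#' acquisition noise.
#'
#' @param shape integer(3), grid size in voxels.
#' @param correlationLength Gaussian kernel sigma in voxels (>= 0.5).
#' @param intensityRange numeric(2) `(lo, hi)`, arbitrary units, `lo < hi`.
#' @param noiseSd additive noise standard deviation, same units (default
#'   2\% of the intensity range, the package's stand-in for an unreported
#'   acquisition SNR).
#' @param spacing numeric(3) voxel size in mm (default 0.35 mm isotropic,
#'   the acquisition resolution the phantom emulates).
#' @param seed integer RNG seed; identical specs generate bitwise
#'   identical volumes.
#' @return a validated list of class `TextureSpec`.
#' @seealso [generateTextureVolume()]
#' @export
textureSpec <- function(shape = c(96, 96, 96), correlationLength = 2,
                        intensityRange = c(0, 100),
                        noiseSd = 0.02 * diff(intensityRange),
                        spacing = c(0.35, 0.35, 0.35), seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 2L)) {
    stop("shape must be 3 positive grid sizes")
  }
  if (!is.finite(correlationLength) || correlationLength < 0.5) {
    stop("correlationLength must be >= 0.5 voxel")
  }
  if (length(intensityRange) != 2L ||
    intensityRange[1] >= intensityRange[2]) {
    stop("intensityRange must be (lo, hi) with lo < hi")
  }
  if (!is.finite(noiseSd) || noiseSd < 0) {
    stop("noiseSd must be >= 0")
  }
  if (any(shape < 8 * correlationLength)) {
    stop(
      "shape too small for correlationLength: every axis must span at ",
      "least 8 x sigma = ", 8 * correlationLength, " voxels"
    )
  }
  structure(
    list(
      shape = shape, correlationLength = as.numeric(correlationLength),
      intensityRange = as.numeric(intensityRange),
      noiseSd = as.numeric(noiseSd), spacing = as.numeric(spacing),
      seed = as.integer(seed)
    ),
    class = "TextureSpec"
  )
}

# smooth unit-range texture without acquisition noise (internal)
.baseTexture <- function(spec) {
  set.seed(spec$seed)
  white <- array(rnorm(prod(spec$shape)), spec$shape)
  sm <- .cpp_gauss_smooth(white, spec$shape, spec$correlationLength)
  lo <- spec$intensityRange[1]
  hi <- spec$intensityRange[2]
  rng <- range(sm)
  arr <- (sm - rng[1]) / (rng[2] - rng[1]) * (hi - lo) + lo
  array(arr, spec$shape)
}

#' Generate a smooth random texture volume
#'
#' White Gaussian noise is low-pass filtered with a Gaussian kernel of
#' sigma `correlationLength` voxels, rescaled to `intensityRange`, and
#' independent additive Gaussian noise of sd `noiseSd` is superimposed.
#' Generation is bitwise reproducible from the spec seed.
#'
#' @param spec a [textureSpec()].
#' @param noiseSeed optional separate seed for the additive noise
#'   realization (defaults to the spec seed; used to draw independent
#'   acquisitions of one underlying scene).
#' @return a [Volume].
#' @examples
#' v <- generateTextureVolume(textureSpec(shape = c(24, 24, 24), seed = 7))
#' @export
generateTextureVolume <- function(spec, noiseSeed = NULL) {
  arr <- .baseTexture(spec)
  if (spec$noiseSd > 0) {
    set.seed(if (is.null(noiseSeed)) spec$seed else as.integer(noiseSeed))
    arr <- arr + array(rnorm(length(arr), sd = spec$noiseSd), spec$shape)
  }
  Volume(arr, spacing = spec$spacing)
}

#' Warp a volume by a parametric model
#'
#' Produces the deformed acquisition of a scene whose material motion is
#' `x = phi(X)`: image content is displaced by the model's displacement
#' field, i.e. `out(x) = vol(phi^{-1}(x))`, with grey levels resampled by
#' tricubic interpolation. An integer translation therefore shifts voxels
#' exactly: translation (2,0,0) gives `out[i,j,k] = vol[i-2,j,k]`.
#' Output voxels whose preimage falls outside the tricubic-supportable
#' interior are set to `fill` and flagged in the returned domain mask.
#'
#' @param vol a [Volume].
#' @param model a [WarpModel] (finite over the volume domain).
#' @param fill intensity for out-of-domain voxels.
#' @return list with `volume` (the warped [Volume]) and `inDomain`
#'   (3D logical array, FALSE where `fill` was substituted).
#' @seealso [evalWarp()], [applyRigid()]
#' @export
warpVolume <- function(vol, model, fill = 0) {
  d <- dim(vol@data)
  x <- as.matrix(expand.grid(
    0:(d[1] - 1L), 0:(d[2] - 1L), 0:(d[3] - 1L)
  ))
  dimnames(x) <- NULL
  X <- .invertWarp(model, x)
  res <- .cpp_tricubic_fill(vol@data, d, X, fill)
  out <- Volume(array(res$values, d),
    spacing = vol@spacing, origin = vol@origin, axes = vol@axes
  )
  list(volume = out, inDomain = array(res$in_domain, d))
}

# trilinear sample of a scalar grid at fractional 0-based coords (clamped)
.trilinear <- function(arr, pts) {
  d <- dim(arr)
  cl <- function(v, n) pmin(pmax(v, 0), n - 1)
  x <- cl(pts[, 1], d[1]); y <- cl(pts[, 2], d[2]); z <- cl(pts[, 3], d[3])
  x0 <- pmin(floor(x), d[1] - 2); y0 <- pmin(floor(y), d[2] - 2)
  z0 <- pmin(floor(z), d[3] - 2)
  tx <- x - x0; ty <- y - y0; tz <- z - z0
  g <- function(a, b, c) arr[cbind(x0 + a + 1, y0 + b + 1, z0 + c + 1)]
  (1 - tz) * ((1 - ty) * ((1 - tx) * g(0, 0, 0) + tx * g(1, 0, 0)) +
    ty * ((1 - tx) * g(0, 1, 0) + tx * g(1, 1, 0))) +
    tz * ((1 - ty) * ((1 - tx) * g(0, 0, 1) + tx * g(1, 0, 1)) +
      ty * ((1 - tx) * g(0, 1, 1) + tx * g(1, 1, 1)))
}

# cosine-taper blend weight from the Euclidean distance to the mask
.blendWeight <- function(mask, taperWidth) {
  d <- dim(mask)
  if (taperWidth <= 0) {
    return(array(as.numeric(mask), d))
  }
  dist <- sqrt(.cpp_edt_sq(mask, d))
  w <- ifelse(dist >= taperWidth, 0, 0.5 * (1 + cos(pi * dist / taperWidth)))
  w[mask] <- 1
  array(w, d)
}

#' Generate a knee-like phantom scene with known ground truth
#'
#' Builds a reference texture, an ellipsoidal-wedge "meniscus" mask and a
#' block "bone" mask, then a deformed acquisition: the meniscus model's
#' displacement applies fully inside the meniscus mask, decays to zero
#' over a cosine-taper shell of `taperWidth` voxels, is identically zero
#' inside the bone (the bones are stationary), and the whole deformed
#' volume is then rigidly perturbed by `bonePerturbation` (emulating
#' inter-acquisition repositioning that registration must undo). The
#' reference and deformed volumes carry independent noise realizations.
#'
#' @param spec a [textureSpec()]; its `seed` fixes the underlying scene.
#' @param meniscusModel [WarpModel] of the imposed meniscus motion
#'   (voxel units).
#' @param bonePerturbation rigid [WarpModel] applied to the whole deformed
#'   volume (default: identity).
#' @param noiseSeeds integer(2), seeds of the reference / deformed noise
#'   realizations.
#' @param taperWidth blend shell width in voxels (0 reproduces an abrupt,
#'   lesion-like discontinuity at the mask boundary).
#' @param geometry optional list overriding the default mask geometry;
#'   entries `meniscusCenter`, `meniscusSemiAxes`, `wedgeAngle` (degrees,
#'   full opening), `boneLo`, `boneHi` (fractional corners of the block),
#'   all in fractions of the grid.
#' @return a [PhantomScene].
#' @seealso [truthField()]
#' @export
generateKneePhantom <- function(spec, meniscusModel,
                                bonePerturbation = rigidWarp(),
                                noiseSeeds = c(spec$seed + 1000L,
                                  spec$seed + 2000L),
                                taperWidth = 4,
                                geometry = list()) {
  d <- spec$shape
  geo <- modifyList(list(
    meniscusCenter = c(0.5, 0.5, 0.64),
    meniscusSemiAxes = c(0.30, 0.30, 0.10),
    wedgeAngle = 120,
    boneLo = c(0.20, 0.20, 0.14),
    boneHi = c(0.80, 0.80, 0.32)
  ), geometry)

  idx <- as.matrix(expand.grid(0:(d[1] - 1L), 0:(d[2] - 1L), 0:(d[3] - 1L)))
  dimnames(idx) <- NULL
  cm <- geo$meniscusCenter * (d - 1)
  semi <- geo$meniscusSemiAxes * d
  rel <- sweep(idx, 2, cm)
  inEll <- (rel[, 1] / semi[1])^2 + (rel[, 2] / semi[2])^2 +
    (rel[, 3] / semi[3])^2 <= 1
  ang <- atan2(rel[, 2], rel[, 1]) * 180 / pi
  menis <- array(inEll & abs(ang) <= geo$wedgeAngle / 2, d)
  lo <- floor(geo$boneLo * (d - 1))
  hi <- ceiling(geo$boneHi * (d - 1))
  bone <- array(FALSE, d)
  bone[
    (lo[1]:hi[1]) + 1L, (lo[2]:hi[2]) + 1L, (lo[3]:hi[3]) + 1L
  ] <- TRUE
  if (!any(menis)) {
    stop("meniscus mask is empty for this geometry")
  }
  if (any(menis & bone)) {
    stop("overlapping masks: meniscus and bone regions intersect")
  }
  occ <- idx[menis | bone, , drop = FALSE]
  if (any(apply(occ, 2, min) < 8) ||
    any((d - 1) - apply(occ, 2, max) < 8)) {
    stop("meniscus and bone regions must keep >= 8-voxel margins")
  }

  w <- .blendWeight(menis, taperWidth)
  w[bone] <- 0

  base <- .baseTexture(spec)

  # deformed = bonePerturbation o phi_blend, inverted per output voxel:
  # first undo the rigid perturbation exactly, then invert the blended
  # meniscus field by fixed point (the blend weight is sampled
  # trilinearly at fractional positions).
  y <- .invertWarp(bonePerturbation, idx)
  X <- y
  for (it in 1:60) {
    u <- warpDisplacement(meniscusModel, X) * .trilinear(w, X)
    Xn <- y - u
    stepMax <- max(abs(Xn - X))
    X <- Xn
    if (stepMax < 1e-10) break
  }
  res <- .cpp_tricubic_fill(base, d, X, 0)

  set.seed(as.integer(noiseSeeds[1]))
  refArr <- base + if (spec$noiseSd > 0) {
    array(rnorm(prod(d), sd = spec$noiseSd), d)
  } else {
    0
  }
  set.seed(as.integer(noiseSeeds[2]))
  defArr <- array(res$values, d) + if (spec$noiseSd > 0) {
    array(rnorm(prod(d), sd = spec$noiseSd), d)
  } else {
    0
  }

  new("PhantomScene",
    reference = Volume(refArr, spacing = spec$spacing),
    deformed = Volume(defArr, spacing = spec$spacing),
    meniscusMask = LabelMask(menis, spacing = spec$spacing),
    boneMask = LabelMask(bone, spacing = spec$spacing),
    truthModel = meniscusModel,
    bonePerturbation = bonePerturbation,
    blendWeight = w,
    inDomain = array(res$in_domain, d),
    provenance = list(
      spec = unclass(spec), noiseSeeds = as.integer(noiseSeeds),
      taperWidth = taperWidth, geometry = geo
    )
  )
}

#' Ground-truth displacement at given nodes of a phantom scene
#'
#' Evaluates the blended truth field (before the bone perturbation) at
#' node positions: `u(X) = weight(X) * (phi(X) - X)`. At nodes inside the
#' meniscus mask this equals the meniscus model's displacement exactly;
#' inside the bone mask it is exactly zero.
#'
#' @param scene a [PhantomScene].
#' @param nodes n x 3 matrix of 0-based voxel coordinates (integer nodes
#'   use stored blend weights exactly; fractional positions interpolate
#'   the weight trilinearly).
#' @return n x 3 matrix of truth displacement in voxels.
#' @export
truthField <- function(scene, nodes) {
  if (is.null(dim(nodes))) {
    nodes <- matrix(nodes, ncol = 3)
  }
  warpDisplacement(scene@truthModel, nodes) *
    .trilinear(scene@blendWeight, nodes)
}
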