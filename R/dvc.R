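# Subset-based volume correlation: configuration, similarity criterion,
# tricubic sampling, exhaustive integer search, Gauss-Newton subvoxel
# refinement, and the per-ROI driver.

#' Construct a DVC configuration
#'
#' Defaults size the engine to the bundled 96^3 phantom at 0.35 mm: a
#' 17^3 correlation sub-volume, one measurement node every 8 voxels, a
#' 10-voxel integer search ball, pure-translation subset shape functions,
#' and a 0.75 ZNCC validity floor.
#'
#' @param subsetHalfWidth integer h; subset edge is `2h + 1` voxels.
#' @param gridStep node spacing in voxels.
#' @param searchRadius integer search ball radius in voxels.
#' @param shapeOrder 0 (pure translation) or 1 (affine subset).
#' @param correlationFloor ZNCC validity threshold in (0, 1).
#' @param tol Gauss-Newton step-norm convergence tolerance (voxels).
#' @param maxIter maximum Gauss-Newton iterations.
#' @param prefilterSigma Gaussian prefilter sigma in voxels applied to
#'   both volumes before matching (0 disables). Matching two
#'   independently-noisy acquisitions with an interpolating kernel
#'   creates spurious correlation optima at fractional offsets (the
#'   interpolated noise has reduced variance there); a ~1 voxel prefilter
#'   band-limits the noise and removes the artifact.
#' @return a [DVCConfig].
#' @export
dvcConfig <- function(subsetHalfWidth = 8L, gridStep = 8L, searchRadius = 10L,
                      shapeOrder = 0L, correlationFloor = 0.75, tol = 1e-4,
                      maxIter = 50L, prefilterSigma = 1.0) {
  new("DVCConfig",
    subsetHalfWidth = as.integer(subsetHalfWidth),
    gridStep = as.integer(gridStep),
    searchRadius = as.integer(searchRadius),
    shapeOrder = as.integer(shapeOrder),
    correlationFloor = as.numeric(correlationFloor),
    tol = as.numeric(tol), maxIter = as.integer(maxIter),
    prefilterSigma = as.numeric(prefilterSigma)
  )
}

#' Zero-mean normalized cross-correlation of two blocks
#'
#' Invariant to affine intensity rescaling of either block; returns a
#' value in [-1, 1]. A block with zero intensity variance is an error.
#'
#' @param a,b numeric arrays of identical shape.
#' @return scalar ZNCC.
#' @examples
#' a <- array(rnorm(27), c(3, 3, 3))
#' zncc(a, 2 * a + 5) # exactly 1
#' @export
zncc <- function(a, b) {
  if (!identical(dim(a), dim(b)) || length(a) != length(b)) {
    stop("blocks must have identical shape")
  }
  ac <- as.numeric(a) - mean(a)
  bc <- as.numeric(b) - mean(b)
  sa <- sum(ac^2)
  sb <- sum(bc^2)
  if (sa <= 0 || sb <= 0) {
    stop("textureless subset: zero intensity variance")
  }
  sum(ac * bc) / sqrt(sa * sb)
}

#' Tricubic grey-level interpolation
#'
#' Separable piecewise cubic interpolation on a 4-point stencil per axis
#' (cubic Lagrange): exact at grid nodes and reproduces polynomial
#' volumes up to degree 3 exactly. Every point must lie at least one
#' voxel inside the grid boundary so the 4^3 support exists; an
#' out-of-support point is an error naming the offender.
#'
#' @param vol a [Volume] (or 3D array).
#' @param points n x 3 matrix of fractional 0-based voxel coordinates.
#' @return numeric(n) interpolated intensities.
#' @export
tricubicInterpolate <- function(vol, points) {
  arr <- if (is(vol, "Volume")) vol@data else vol
  if (is.null(dim(points))) {
    points <- matrix(points, ncol = 3)
  }
  .cpp_tricubic(arr, dim(arr), as.matrix(points))
}

.checkPair <- function(reference, deformed) {
  checkGeometry(reference, deformed)
  invisible(dim(reference@data))
}

#' Integer-voxel subset search
#'
#' Exhaustively scores every integer offset within the search ball
#' (`|offset| <= searchRadius`) by the ZNCC between the reference subset
#' at `node` and the deformed subset at `node + offset`, and returns the
#' argmax. Ties are broken by the smaller offset norm, then
#' lexicographically.
#'
#' @param reference,deformed [Volume]s sharing one grid.
#' @param node integer(3), 0-based subset centre.
#' @param cfg a [dvcConfig()].
#' @return list with `offset` (integer(3)), `correlation`.
#' @seealso [subvoxelRefine()], [correlateVolumes()]
#' @export
integerSearch <- function(reference, deformed, node, cfg = dvcConfig()) {
  d <- .checkPair(reference, deformed)
  r <- .cpp_integer_search(
    reference@data, deformed@data, d, as.integer(node),
    cfg@subsetHalfWidth, cfg@searchRadius
  )
  if (r$status == 2L) {
    stop("subset or search window exceeds the volume bounds at node (",
      paste(node, collapse = ", "), ")")
  }
  if (r$status == 1L) {
    stop("textureless subset: zero intensity variance at node (",
      paste(node, collapse = ", "), ")")
  }
  list(offset = r$offset, correlation = r$correlation)
}

#' Subvoxel subset refinement
#'
#' Starting from the integer-search offset, minimises the zero-mean
#' normalized sum of squared differences (ZNSSD) between the reference
#' subset and the tricubic-sampled deformed subset by Gauss-Newton
#' iteration (each step solves the normal equations of the linearized
#' residual). `shapeOrder` 0 optimises a pure subset translation;
#' `shapeOrder` 1 adds a 3x3 displacement gradient. Iteration stops when
#' the step norm falls below `tol` or after `maxIter` iterations; a step
#' norm growing for 3 consecutive iterations is flagged as divergence and
#' the best iterate is returned.
#'
#' @param reference,deformed [Volume]s sharing one grid.
#' @param node integer(3), 0-based subset centre.
#' @param init integer(3) initial offset (from [integerSearch()]).
#' @param cfg a [dvcConfig()].
#' @return list with `u` (numeric(3), voxels), `uInt` (the init),
#'   `correlation` (final ZNCC), `iterations`, `converged`.
#' @export
subvoxelRefine <- function(reference, deformed, node, init = c(0L, 0L, 0L),
                           cfg = dvcConfig()) {
  d <- .checkPair(reference, deformed)
  r <- .cpp_refine(
    reference@data, deformed@data, d, as.integer(node),
    as.numeric(init), cfg@subsetHalfWidth, cfg@tol, cfg@maxIter,
    cfg@shapeOrder
  )
  if (r$status == 1L) {
    stop("textureless subset: zero intensity variance at node (",
      paste(node, collapse = ", "), ")")
  }
  list(
    u = as.numeric(r$u), uInt = as.integer(round(init)),
    correlation = r$correlation, iterations = r$iterations,
    converged = isTRUE(r$converged)
  )
}

#' Correlate a volume pair over a region of interest
#'
#' Lays a regular measurement grid of step `gridStep` voxels over the
#' bounding box of the ROI, keeps nodes whose subset centre lies in the
#' ROI and whose subset plus search window fits inside the volume, and
#' for each runs [integerSearch()] followed by [subvoxelRefine()]. A node
#' is `valid` when the refinement converged and its final ZNCC reaches
#' `correlationFloor`. Node order is fixed raster order (first axis
#' fastest), and the result is deterministic given the inputs.
#'
#' @param reference,deformed [Volume]s sharing one grid.
#' @param roi a [LabelMask] on the same grid.
#' @param cfg a [dvcConfig()].
#' @param subsetInRoi when TRUE, keep only nodes whose subset (plus the
#'   prefilter support, radius `subsetHalfWidth + 4 prefilterSigma`) lies
#'   entirely inside the ROI, so no matched texture straddles the
#'   structure boundary. Edge subsets mix moving and static texture and
#'   bias the estimate toward zero; restricting to interior subsets is
#'   the standard remedy when the ROI is a segmented anatomical
#'   structure. Default FALSE (membership of the subset centre suffices).
#' @return a [DisplacementField].
#' @examples
#' spec <- textureSpec(shape = c(48, 48, 48), noiseSd = 0, seed = 3)
#' ref <- generateTextureVolume(spec)
#' def <- warpVolume(ref, translationWarp(c(0.4, 0, 0)))$volume
#' roi <- LabelMask(array(TRUE, c(48, 48, 48)), spacing = spacing(ref))
#' f <- correlateVolumes(ref, def, roi, dvcConfig(
#'   subsetHalfWidth = 5,
#'   gridStep = 12, searchRadius = 2
#' ))
#' head(records(f, validOnly = TRUE))
#' @export
correlateVolumes <- function(reference, deformed, roi, cfg = dvcConfig(),
                             subsetInRoi = FALSE) {
  d <- .checkPair(reference, deformed)
  checkGeometry(reference, roi)
  m <- roi@data
  if (!any(m)) {
    stop("ROI is empty")
  }
  w <- which(m, arr.ind = TRUE) - 1L # 0-based
  bb0 <- apply(w, 2, min)
  bb1 <- apply(w, 2, max)
  gi <- seq(bb0[1], bb1[1], by = cfg@gridStep)
  gj <- seq(bb0[2], bb1[2], by = cfg@gridStep)
  gk <- seq(bb0[3], bb1[3], by = cfg@gridStep)
  nodes <- as.matrix(expand.grid(gi, gj, gk)) # raster order, i fastest
  dimnames(nodes) <- NULL
  inRoi <- m[nodes + 1L]
  if (subsetInRoi) {
    distBg2 <- .cpp_edt_sq(!m, d) # squared distance to background
    rad <- cfg@subsetHalfWidth +
      if (cfg@prefilterSigma > 0) ceiling(4 * cfg@prefilterSigma) else 0
    inRoi <- inRoi & distBg2[nodes + 1L] > rad^2
  }
  # nodes must keep the subset + search window in bounds, the tricubic
  # support, and (when prefiltering) the smoothing kernel support, since
  # boundary smoothing does not commute with the deformation
  pad <- if (cfg@prefilterSigma > 0) ceiling(4 * cfg@prefilterSigma) else 0L
  marg <- cfg@subsetHalfWidth + cfg@searchRadius + 1L + as.integer(pad)
  inBounds <- nodes[, 1] >= marg & nodes[, 1] <= d[1] - 1L - marg &
    nodes[, 2] >= marg & nodes[, 2] <= d[2] - 1L - marg &
    nodes[, 3] >= marg & nodes[, 3] <= d[3] - 1L - marg
  keep <- inRoi & inBounds
  if (!any(keep)) {
    stop(
      "ROI too small for subset size: no measurement node keeps the ",
      2L * cfg@subsetHalfWidth + 1L, "^3 subset and +/-", cfg@searchRadius,
      " search window in bounds"
    )
  }
  nodes <- nodes[keep, , drop = FALSE]
  refArr <- reference@data
  defArr <- deformed@data
  if (cfg@prefilterSigma > 0) {
    refArr <- array(.cpp_gauss_smooth(refArr, d, cfg@prefilterSigma), d)
    defArr <- array(.cpp_gauss_smooth(defArr, d, cfg@prefilterSigma), d)
  }
  res <- .cpp_dvc_nodes(
    refArr, defArr, d, nodes,
    cfg@subsetHalfWidth, cfg@searchRadius, cfg@tol, cfg@maxIter,
    cfg@shapeOrder
  )
  sp <- reference@spacing
  conv <- res[, 9] > 0
  corr <- res[, 7]
  recs <- data.frame(
    i = nodes[, 1], j = nodes[, 2], k = nodes[, 3],
    ux_vox = res[, 4], uy_vox = res[, 5], uz_vox = res[, 6],
    ux_mm = res[, 4] * sp[1], uy_mm = res[, 5] * sp[2],
    uz_mm = res[, 6] * sp[3],
    correlation = corr, iterations = as.integer(res[, 8]),
    converged = conv,
    valid = conv & !is.na(corr) & corr >= cfg@correlationFloor
  )
  displacementField(
    recs,
    gridDims = c(length(gi), length(gj), length(gk)),
    gridOrigin = bb0, gridStep = cfg@gridStep,
    spacing = sp, origin = reference@origin
  )
}
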