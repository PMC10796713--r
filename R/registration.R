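# Bone-referenced rigid registration: masked NCC metric, 3-level
# coarse-to-fine pyramid, derivative-free (Nelder-Mead) refinement at
# each level. Same-session same-modality images justify NCC over mutual
# information; the rotation centre is the volume geometric centre, which
# minimises rotation-translation coupling.

#' Construct a rigid transform
#'
#' @param rotation numeric(3) angles in degrees (about X, Y, Z; applied as
#'   `Rz \%*\% Ry \%*\% Rx` about `center`).
#' @param translation numeric(3) in mm.
#' @param center rotation centre in mm.
#' @return a [RigidTransform].
#' @export
rigidTransform <- function(rotation = c(0, 0, 0), translation = c(0, 0, 0),
                           center = c(0, 0, 0)) {
  new("RigidTransform",
    rotation = as.numeric(rotation),
    translation = as.numeric(translation), center = as.numeric(center)
  )
}

#' Map physical points through a rigid transform
#'
#' @param t a [RigidTransform].
#' @param pts n x 3 matrix of positions in mm.
#' @return n x 3 matrix `T(p) = R (p - center) + center + translation`.
#' @export
transformPoints <- function(t, pts) {
  if (is.null(dim(pts))) {
    pts <- matrix(pts, ncol = 3)
  }
  R <- .rotationMatrixDeg(t@rotation)
  sweep(sweep(pts, 2, t@center) %*% t(R), 2, t@center + t@translation, "+")
}

#' Invert a rigid transform
#'
#' @param t a [RigidTransform].
#' @return the [RigidTransform] `t^{-1}` (same centre); composing the two
#'   gives the identity to machine precision.
#' @export
rigidInverse <- function(t) {
  R <- .rotationMatrixDeg(t@rotation)
  rigidTransform(
    rotation = .eulerFromMatrixDeg(t(R)),
    translation = as.numeric(-t(R) %*% t@translation),
    center = t@center
  )
}

#' Compose two rigid transforms
#'
#' @param t2,t1 [RigidTransform]s sharing one centre; the result applies
#'   `t1` first: `T(p) = t2(t1(p))`.
#' @return the composed [RigidTransform].
#' @export
rigidCompose <- function(t2, t1) {
  if (any(abs(t2@center - t1@center) > 1e-9)) {
    stop("transforms must share one rotation centre")
  }
  r2 <- .rotationMatrixDeg(t2@rotation)
  rigidTransform(
    rotation = .eulerFromMatrixDeg(r2 %*% .rotationMatrixDeg(t1@rotation)),
    translation = as.numeric(r2 %*% t1@translation) + t2@translation,
    center = t1@center
  )
}

#' Resample a volume under a rigid transform
#'
#' `out(X) = vol(T(X))` with tricubic grey-level interpolation, so
#' applying the transform recovered by [registerRigid()] aligns the
#' moving volume onto the reference grid. Out-of-domain voxels are set to
#' `fill` and flagged.
#'
#' @param vol a [Volume].
#' @param t a [RigidTransform].
#' @param fill intensity for out-of-domain voxels.
#' @return list with `volume` (the resampled [Volume]) and `inDomain`
#'   (3D logical array).
#' @export
applyRigid <- function(vol, t, fill = 0) {
  d <- dim(vol@data)
  idx <- as.matrix(expand.grid(0:(d[1] - 1L), 0:(d[2] - 1L), 0:(d[3] - 1L)))
  dimnames(idx) <- NULL
  pmm <- sweep(sweep(idx, 2, vol@spacing, "*"), 2, vol@origin, "+")
  q <- transformPoints(t, pmm)
  qvox <- sweep(sweep(q, 2, vol@origin), 2, vol@spacing, "/")
  res <- .cpp_tricubic_fill(vol@data, d, qvox, fill)
  list(
    volume = Volume(array(res$values, d),
      spacing = vol@spacing,
      origin = vol@origin, axes = vol@axes
    ),
    inDomain = array(res$in_domain, d)
  )
}

#' Rigid registration on a stationary reference region
#'
#' Finds the 6-parameter rigid transform maximising the normalized
#' cross-correlation between the reference volume and the moving volume
#' resampled under the transform, evaluated only over the supplied mask
#' (the stationary bone region). A 3-level coarse-to-fine pyramid
#' (Gaussian smoothing + mask striding) with Nelder-Mead refinement at
#' each level is used; an optional user-supplied initial transform seeds
#' the coarsest level, realising a semi-automated workflow without a GUI.
#' If the final masked NCC falls below `metricFloor` the transform is
#' still returned but flagged.
#'
#' @param reference,moving [Volume]s sharing one grid geometry.
#' @param boneMask [LabelMask] of the stationary region (>= 1000 voxels
#'   recommended).
#' @param init optional initial [RigidTransform].
#' @param metricFloor masked-NCC floor below which the result is flagged.
#' @param levels list of `c(smoothSigma, stride)` pairs, coarse to fine.
#'   The finest level keeps a mild smoothing: sampling raw noise through
#'   an interpolating kernel biases the metric optimum, exactly as in
#'   subset matching.
#' @param maxit Nelder-Mead iteration budget per level.
#' @param maxPoints cap on metric sample points per level.
#' @return a [RigidTransform] with the achieved `correlation` and
#'   `metricOk` flag filled in.
#' @seealso [applyRigid()]
#' @export
registerRigid <- function(reference, moving, boneMask, init = NULL,
                          metricFloor = 0.5,
                          levels = list(c(2, 4), c(1, 2), c(0.75, 1)),
                          maxit = c(400L, 300L, 300L),
                          maxPoints = 30000L) {
  d <- .checkPair(reference, moving)
  checkGeometry(reference, boneMask)
  if (!any(boneMask@data)) {
    stop("bone mask is empty")
  }
  sp <- reference@spacing
  org <- reference@origin
  center <- org + (d - 1) / 2 * sp
  coordsAll <- which(boneMask@data, arr.ind = TRUE) - 1L
  par <- if (is.null(init)) {
    rep(0, 6)
  } else {
    c(init@rotation, init@translation)
  }
  ncc <- NA_real_
  for (lv in seq_along(levels)) {
    sig <- levels[[lv]][1]
    stride <- levels[[lv]][2]
    refS <- if (sig > 0) {
      .cpp_gauss_smooth(reference@data, d, sig)
    } else {
      reference@data
    }
    movS <- if (sig > 0) .cpp_gauss_smooth(moving@data, d, sig) else moving@data
    keep <- coordsAll[, 1] %% stride == 0 & coordsAll[, 2] %% stride == 0 &
      coordsAll[, 3] %% stride == 0
    pts <- coordsAll[keep, , drop = FALSE]
    if (nrow(pts) > maxPoints) {
      pts <- pts[seq(1, nrow(pts), length.out = maxPoints), , drop = FALSE]
      pts <- matrix(as.integer(round(pts)), ncol = 3)
    }
    refVals <- refS[pts + 1L]
    pmm <- sweep(sweep(pts, 2, sp, "*"), 2, org, "+")
    obj <- function(p) {
      t <- rigidTransform(p[1:3], p[4:6], center)
      qvox <- sweep(sweep(transformPoints(t, pmm), 2, org), 2, sp, "/")
      v <- .cpp_masked_ncc(refVals, movS, d, qvox)
      if (is.na(v$ncc) || v$n_used < 0.25 * v$n_total) {
        return(2)
      }
      -v$ncc
    }
    opt <- optim(par, obj,
      method = "Nelder-Mead",
      control = list(
        maxit = maxit[min(lv, length(maxit))],
        parscale = c(rep(1, 3), sp), reltol = 1e-10
      )
    )
    par <- opt$par
    ncc <- -opt$value
  }
  out <- rigidTransform(par[1:3], par[4:6], center)
  out@correlation <- ncc
  out@metricOk <- is.finite(ncc) && ncc >= metricFloor
  if (!out@metricOk) {
    warning(
      "registration metric ", format(ncc, digits = 4),
      " below floor ", metricFloor, "; transform flagged"
    )
  }
  out
}

#' Write a rigid transform to JSON
#'
#' Stores rotation (degrees), translation (mm), centre (mm) and the
#' achieved metric value.
#'
#' @param t a [RigidTransform].
#' @param path output `.json` path.
#' @return invisibly, `path`.
#' @export
writeRigidTransform <- function(t, path) {
  jsonlite::write_json(
    list(
      rotation_deg = t@rotation, translation_mm = t@translation,
      center_mm = t@center, metric_ncc = t@correlation,
      metric_ok = t@metricOk
    ),
    path,
    auto_unbox = FALSE, digits = NA
  )
  invisible(path)
}

#' Read a rigid transform from JSON
#'
#' @param path a `.json` file written by [writeRigidTransform()].
#' @return a [RigidTransform].
#' @export
readRigidTransform <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- rigidTransform(j$rotation_deg, j$translation_mm, j$center_mm)
  if (!is.null(j$metric_ncc)) out@correlation <- as.numeric(j$metric_ncc)[1]
  if (!is.null(j$metric_ok)) out@metricOk <- isTRUE(as.logical(j$metric_ok)[1])
  out
}
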