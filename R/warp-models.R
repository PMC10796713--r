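# Parametric warp models: the ground-truth material transformation phi
# used to synthesise deformed volumes. All coordinates and displacements
# are in voxel units (0-based indices).

#' Rigid warp model
#'
#' `phi(X) = R (X - center) + center + translation`, with `R` built from
#' angles in degrees about the X, Y, Z axes (`R = Rz \%*\% Ry \%*\% Rx`).
#'
#' @param rotation numeric(3), degrees.
#' @param translation numeric(3), voxels.
#' @param center numeric(3), rotation centre in voxel coordinates.
#' @return a [WarpModel] of kind "rigid".
#' @export
rigidWarp <- function(rotation = c(0, 0, 0), translation = c(0, 0, 0),
                      center = c(0, 0, 0)) {
  new("WarpModel", kind = "rigid", params = list(
    rotation = as.numeric(rotation), translation = as.numeric(translation),
    center = as.numeric(center)
  ))
}

#' Pure translation warp model
#'
#' Convenience wrapper for a [rigidWarp()] with zero rotation.
#'
#' @param translation numeric(3), voxels.
#' @return a [WarpModel] of kind "rigid".
#' @export
translationWarp <- function(translation) {
  rigidWarp(translation = translation)
}

#' Affine warp model
#'
#' `phi(X) = A X + translation`.
#'
#' @param A 3x3 matrix.
#' @param translation numeric(3), voxels.
#' @return a [WarpModel] of kind "affine".
#' @export
affineWarp <- function(A, translation = c(0, 0, 0)) {
  new("WarpModel", kind = "affine", params = list(
    A = A, translation = as.numeric(translation)
  ))
}

#' Gaussian-bump warp model
#'
#' A smooth localized displacement
#' `u(X) = peak * exp(-|X - center|^2 / (2 sigma^2))`; the field magnitude
#' is bounded by `|peak|` and decays to zero away from the centre.
#'
#' @param center numeric(3), bump centre in voxel coordinates.
#' @param sigma scalar width in voxels.
#' @param peak numeric(3), peak displacement in voxels.
#' @return a [WarpModel] of kind "gaussian_bump".
#' @export
gaussianBumpWarp <- function(center, sigma, peak) {
  new("WarpModel", kind = "gaussian_bump", params = list(
    center = as.numeric(center), sigma = as.numeric(sigma),
    peak = as.numeric(peak)
  ))
}

#' Composite warp model
#'
#' Ordered composition; the first model is applied first:
#' `phi = phi_n o ... o phi_1`.
#'
#' @param ... [WarpModel] objects, or a single list of them.
#' @return a [WarpModel] of kind "composite".
#' @export
compositeWarp <- function(...) {
  models <- list(...)
  if (length(models) == 1L && is.list(models[[1]]) &&
    !is(models[[1]], "WarpModel")) {
    models <- models[[1]]
  }
  new("WarpModel", kind = "composite", params = list(models = models))
}

.rotationMatrixDeg <- function(angles) {
  a <- angles * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  rz %*% ry %*% rx
}

.eulerFromMatrixDeg <- function(R) {
  # inverse of .rotationMatrixDeg (Rz Ry Rx convention)
  b <- asin(max(-1, min(1, -R[3, 1])))
  a <- atan2(R[3, 2], R[3, 3])
  cc <- atan2(R[2, 1], R[1, 1])
  c(a, b, cc) * 180 / pi
}

#' Evaluate a warp model at reference positions
#'
#' @param model a [WarpModel].
#' @param X n x 3 matrix of 0-based voxel coordinates (a numeric(3) is
#'   treated as a single point).
#' @return n x 3 matrix of deformed positions `phi(X)` in voxel
#'   coordinates.
#' @seealso [warpDisplacement()]
#' @export
evalWarp <- function(model, X) {
  if (is.null(dim(X))) {
    X <- matrix(X, ncol = 3)
  }
  p <- model@params
  switch(model@kind,
    rigid = {
      R <- .rotationMatrixDeg(p$rotation)
      sweep(
        sweep(X, 2, p$center) %*% t(R), 2,
        p$center + p$translation, "+"
      )
    },
    affine = sweep(X %*% t(p$A), 2, p$translation, "+"),
    gaussian_bump = {
      d2 <- sweep(X, 2, p$center)
      w <- exp(-rowSums(d2^2) / (2 * p$sigma^2))
      X + outer(w, p$peak)
    },
    composite = {
      for (m in p$models) X <- evalWarp(m, X)
      X
    }
  )
}

#' Displacement field of a warp model
#'
#' @param model a [WarpModel].
#' @param X n x 3 matrix of 0-based voxel coordinates.
#' @return n x 3 matrix `u(X) = phi(X) - X` in voxels.
#' @export
warpDisplacement <- function(model, X) {
  if (is.null(dim(X))) {
    X <- matrix(X, ncol = 3)
  }
  evalWarp(model, X) - X
}

# Invert phi at target positions x: returns X with phi(X) = x.
# Rigid and affine maps (and compositions of them) are inverted exactly;
# anything else falls back to fixed-point iteration X <- x - u(X), which
# contracts whenever |grad u| < 1 (true for all phantom fields used here).
.invertWarp <- function(model, x, maxIter = 60, tol = 1e-12) {
  p <- model@params
  if (model@kind == "rigid") {
    R <- .rotationMatrixDeg(p$rotation)
    return(sweep(
      sweep(x, 2, p$center + p$translation) %*% R, 2, p$center, "+"
    ))
  }
  if (model@kind == "affine") {
    return(t(solve(p$A, t(sweep(x, 2, p$translation)))))
  }
  if (model@kind == "composite" &&
    all(vapply(p$models, function(m) m@kind %in% c("rigid", "affine"),
      logical(1)))) {
    for (m in rev(p$models)) x <- .invertWarp(m, x)
    return(x)
  }
  X <- x
  for (it in seq_len(maxIter)) {
    step <- evalWarp(model, X) - x
    X <- X - step
    if (max(abs(step)) < tol) break
  }
  X
}
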