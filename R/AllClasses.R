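#' Volume: a 3D scalar image with voxel geometry
#'
#' Container for one 3D grey-level image together with its voxel geometry:
#' per-axis voxel size in mm, the physical position of voxel (0,0,0), and
#' ordered anatomical axis labels. Holds the grey levels `f(X)` of the
#' reference state or `g(x)` of the deformed state of a correlation pair.
#'
#' @slot data 3D numeric array of intensities (arbitrary units).
#' @slot spacing numeric(3), voxel size per axis in mm; all > 0.
#' @slot origin numeric(3), physical position (mm) of voxel (0,0,0).
#' @slot axes character(3), anatomical direction labels in axis order.
#'
#' @seealso [Volume()], [readVolume()], [writeVolume()]
#' @exportClass Volume
setClass("Volume",
  representation(
    data = "array",
    spacing = "numeric",
    origin = "numeric",
    axes = "character"
  ),
  prototype(
    spacing = c(1, 1, 1),
    origin = c(0, 0, 0),
    axes = c("lateromedial", "anteroposterior", "axial")
  )
)

setValidity("Volume", function(object) {
  d <- object@data
  if (length(dim(d)) != 3L) {
    return("data must be a 3D array")
  }
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
    any(object@spacing <= 0)) {
    return("spacing must be 3 positive finite values (mm)")
  }
  if (length(object@origin) != 3L || any(!is.finite(object@origin))) {
    return("origin must be 3 finite values (mm)")
  }
  if (length(object@axes) != 3L) {
    return("axes must be 3 direction labels")
  }
  if (any(!is.finite(d))) {
    return("intensities must be finite")
  }
  TRUE
})

#' LabelMask: a binary region-of-interest on a volume grid
#'
#' Boolean 3D grid sharing shape, spacing and origin with its companion
#' [Volume]. Used for the manually-segmented structure of interest (e.g.
#' the medial meniscus) and for the stationary bone reference region.
#'
#' @slot data 3D logical array.
#' @slot spacing numeric(3), voxel size per axis in mm.
#' @slot origin numeric(3), physical position (mm) of voxel (0,0,0).
#'
#' @seealso [LabelMask()], [checkGeometry()]
#' @exportClass LabelMask
setClass("LabelMask",
  representation(
    data = "array",
    spacing = "numeric",
    origin = "numeric"
  ),
  prototype(spacing = c(1, 1, 1), origin = c(0, 0, 0))
)

setValidity("LabelMask", function(object) {
  d <- object@data
  if (length(dim(d)) != 3L || !is.logical(d)) {
    return("data must be a 3D logical array")
  }
  if (any(is.na(d))) {
    return("mask values must be TRUE/FALSE, not NA")
  }
  if (length(object@spacing) != 3L || any(object@spacing <= 0)) {
    return("spacing must be 3 positive values (mm)")
  }
  if (length(object@origin) != 3L || any(!is.finite(object@origin))) {
    return("origin must be 3 finite values (mm)")
  }
  TRUE
})

#' WarpModel: parametric ground-truth material transformation
#'
#' Describes the material transformation `phi` mapping reference positions
#' `X` (0-based voxel coordinates) to deformed positions `x = phi(X)`,
#' used to synthesise deformed volumes with known displacement
#' `u(X) = phi(X) - X`. Kinds:
#' \describe{
#'   \item{rigid}{rotation (degrees, applied about `center` as
#'     `Rz \%*\% Ry \%*\% Rx`) plus translation (voxels).}
#'   \item{affine}{3x3 matrix `A` and translation `t`: `phi(X) = A X + t`.}
#'   \item{gaussian_bump}{`phi(X) = X + peak * exp(-|X - center|^2 / (2 sigma^2))`;
#'     the field magnitude never exceeds `|peak|`.}
#'   \item{composite}{ordered composition of models (first applied first).}
#' }
#'
#' @slot kind character, one of "rigid", "affine", "gaussian_bump", "composite".
#' @slot params named list of kind-specific parameters.
#'
#' @seealso [rigidWarp()], [affineWarp()], [gaussianBumpWarp()],
#'   [compositeWarp()], [evalWarp()], [warpVolume()]
#' @exportClass WarpModel
setClass("WarpModel",
  representation(kind = "character", params = "list")
)

setValidity("WarpModel", function(object) {
  if (!object@kind %in% c("rigid", "affine", "gaussian_bump", "composite")) {
    return("kind must be rigid, affine, gaussian_bump or composite")
  }
  p <- object@params
  switch(object@kind,
    rigid = {
      if (length(p$rotation) != 3L || length(p$translation) != 3L ||
        length(p$center) != 3L) {
        return("rigid model needs rotation(3), translation(3), center(3)")
      }
      if (any(!is.finite(c(p$rotation, p$translation, p$center)))) {
        return("rigid parameters must be finite")
      }
    },
    affine = {
      if (!is.matrix(p$A) || any(dim(p$A) != c(3L, 3L)) ||
        length(p$translation) != 3L) {
        return("affine model needs A(3x3) and translation(3)")
      }
      if (any(!is.finite(c(p$A, p$translation)))) {
        return("affine parameters must be finite")
      }
    },
    gaussian_bump = {
      if (length(p$center) != 3L || length(p$peak) != 3L ||
        length(p$sigma) != 1L) {
        return("gaussian_bump model needs center(3), sigma(1), peak(3)")
      }
      if (!is.finite(p$sigma) || p$sigma <= 0) {
        return("gaussian_bump sigma must be positive")
      }
    },
    composite = {
      if (length(p$models) < 1L ||
        !all(vapply(p$models, function(m) is(m, "WarpModel"), logical(1)))) {
        return("composite model needs a non-empty list of WarpModels")
      }
    }
  )
  TRUE
})

#' DVCConfig: tunable parameters of the subset correlation engine
#'
#' @slot subsetHalfWidth integer h; the correlation sub-volume is a cube of
#'   edge `2h + 1` voxels centred on the measurement node (edge >= 7).
#' @slot gridStep integer, spacing of measurement nodes in voxels.
#' @slot searchRadius integer, radius (voxels) of the integer search ball.
#' @slot shapeOrder 0 for pure subset translation, 1 for an affine subset
#'   (translation + 3x3 displacement gradient).
#' @slot correlationFloor ZNCC below which a node is marked invalid.
#' @slot tol Gauss-Newton convergence tolerance on the step norm (voxels).
#' @slot maxIter maximum Gauss-Newton iterations per node.
#' @slot prefilterSigma Gaussian prefilter sigma (voxels) applied to both
#'   volumes by [correlateVolumes()] before matching; 0 disables. The
#'   prefilter suppresses the spurious subvoxel optima that interpolating
#'   uncorrelated acquisition noise otherwise creates.
#'
#' @seealso [dvcConfig()], [correlateVolumes()]
#' @exportClass DVCConfig
setClass("DVCConfig",
  representation(
    subsetHalfWidth = "integer",
    gridStep = "integer",
    searchRadius = "integer",
    shapeOrder = "integer",
    correlationFloor = "numeric",
    tol = "numeric",
    maxIter = "integer",
    prefilterSigma = "numeric"
  )
)

setValidity("DVCConfig", function(object) {
  if (2L * object@subsetHalfWidth + 1L < 7L) {
    return("subset edge 2h+1 must be at least 7 voxels")
  }
  if (object@gridStep < 1L) {
    return("gridStep must be >= 1")
  }
  if (object@searchRadius < 1L) {
    return("searchRadius must be >= 1")
  }
  if (!object@shapeOrder %in% c(0L, 1L)) {
    return("shapeOrder must be 0 or 1")
  }
  if (object@correlationFloor <= 0 || object@correlationFloor >= 1) {
    return("correlationFloor must lie in (0, 1)")
  }
  if (!is.finite(object@tol) || object@tol <= 0) {
    return("tol must be > 0")
  }
  if (object@maxIter < 1L) {
    return("maxIter must be >= 1")
  }
  if (length(object@prefilterSigma) != 1L ||
    !is.finite(object@prefilterSigma) || object@prefilterSigma < 0) {
    return("prefilterSigma must be a finite value >= 0")
  }
  TRUE
})

#' DisplacementField: per-node displacement vectors with quality flags
#'
#' One row per measurement node: 0-based node voxel indices, displacement
#' in voxels and mm (`u_mm = u_vox * spacing`, componentwise), the final
#' ZNCC, iteration count, convergence flag and overall validity
#' (`valid = converged & correlation >= correlationFloor`). The nodes live
#' on a regular grid of step `gridStep` voxels; `gridOrigin` is the node
#' index of the first grid position and `gridDims` the number of grid
#' positions per axis (nodes dropped for bounds or ROI membership are
#' absent from `records`).
#'
#' @slot records data.frame with columns i, j, k, ux_vox, uy_vox, uz_vox,
#'   ux_mm, uy_mm, uz_mm, correlation, iterations, converged, valid.
#' @slot gridDims integer(3), number of grid nodes per axis.
#' @slot gridOrigin integer(3), voxel index of the first grid node.
#' @slot gridStep integer(1), node spacing in voxels.
#' @slot spacing numeric(3), voxel size (mm) of the parent volume.
#' @slot origin numeric(3), origin (mm) of the parent volume.
#'
#' @seealso [correlateVolumes()], [writeDisplacementField()]
#' @exportClass DisplacementField
setClass("DisplacementField",
  representation(
    records = "data.frame",
    gridDims = "integer",
    gridOrigin = "integer",
    gridStep = "integer",
    spacing = "numeric",
    origin = "numeric"
  )
)

setValidity("DisplacementField", function(object) {
  need <- c(
    "i", "j", "k", "ux_vox", "uy_vox", "uz_vox", "ux_mm", "uy_mm",
    "uz_mm", "correlation", "iterations", "converged", "valid"
  )
  if (!all(need %in% names(object@records))) {
    return(paste(
      "records must have columns:",
      paste(need, collapse = ", ")
    ))
  }
  r <- object@records
  for (a in 1:3) {
    vox <- r[[c("ux_vox", "uy_vox", "uz_vox")[a]]]
    mm <- r[[c("ux_mm", "uy_mm", "uz_mm")[a]]]
    ok <- is.na(vox) | is.na(mm) |
      abs(mm - vox * object@spacing[a]) <= 1e-9 * (1 + abs(mm))
    if (!all(ok)) {
      return("u_mm must equal u_vox * spacing componentwise")
    }
  }
  cc <- r$correlation
  if (any(!is.na(cc) & (cc < -1 - 1e-12 | cc > 1 + 1e-12))) {
    return("correlation must lie in [-1, 1]")
  }
  if (any(r$valid & is.na(cc))) {
    return("valid records must carry a correlation value")
  }
  if (length(object@gridDims) != 3L || length(object@gridOrigin) != 3L ||
    length(object@gridStep) != 1L || object@gridStep < 1L) {
    return("grid geometry must be gridDims(3), gridOrigin(3), gridStep(1)")
  }
  TRUE
})

#' RigidTransform: a 6-parameter rigid-body transform
#'
#' Rotation angles in degrees applied about a fixed centre (mm) in the
#' order `R = Rz \%*\% Ry \%*\% Rx`, followed by a translation in mm:
#' `T(p) = R (p - center) + center + translation`. Composition with its
#' inverse is the identity to machine precision.
#'
#' @slot rotation numeric(3), angles about the X, Y, Z axes in degrees.
#' @slot translation numeric(3), mm.
#' @slot center numeric(3), rotation centre in mm.
#' @slot correlation achieved masked NCC of the registration that produced
#'   the transform (NA when constructed directly).
#' @slot metricOk FALSE when the registration metric fell below its
#'   configured floor.
#'
#' @seealso [rigidTransform()], [registerRigid()], [applyRigid()]
#' @exportClass RigidTransform
setClass("RigidTransform",
  representation(
    rotation = "numeric",
    translation = "numeric",
    center = "numeric",
    correlation = "numeric",
    metricOk = "logical"
  ),
  prototype(correlation = NA_real_, metricOk = TRUE)
)

setValidity("RigidTransform", function(object) {
  if (length(object@rotation) != 3L || any(!is.finite(object@rotation))) {
    return("rotation must be 3 finite angles (degrees)")
  }
  if (length(object@translation) != 3L || any(!is.finite(object@translation))) {
    return("translation must be 3 finite values (mm)")
  }
  if (length(object@center) != 3L || any(!is.finite(object@center))) {
    return("center must be 3 finite values (mm)")
  }
  TRUE
})

#' PhantomScene: a synthetic loading experiment with known ground truth
#'
#' A reference texture volume, a deformed acquisition of the same scene,
#' binary masks of the mobile structure (meniscus) and of the stationary
#' bone block, and the exact ground truth that generated the deformation:
#' the meniscus [WarpModel], the cosine-taper blend weight that confines
#' the field to the structure (1 inside the meniscus mask, 0 in bone), and
#' the rigid perturbation applied to the whole deformed volume to exercise
#' registration. The truth displacement (before the bone perturbation) at
#' voxel X is `weight(X) * (phi(X) - X)`; it is identically zero inside
#' the bone mask.
#'
#' @slot reference [Volume], reference-state acquisition (with noise).
#' @slot deformed [Volume], loaded-state acquisition (warped, perturbed,
#'   independent noise realization).
#' @slot meniscusMask [LabelMask] of the mobile structure.
#' @slot boneMask [LabelMask] of the stationary reference block.
#' @slot truthModel [WarpModel] of the imposed meniscus motion.
#' @slot bonePerturbation [WarpModel] (rigid) applied to the whole
#'   deformed volume after warping.
#' @slot blendWeight 3D numeric array in [0, 1].
#' @slot inDomain 3D logical array, FALSE where the deformed volume was
#'   filled because its preimage left the interpolation support.
#' @slot provenance named list echoing all generation parameters and seeds.
#'
#' @seealso [generateKneePhantom()], [truthField()]
#' @exportClass PhantomScene
setClass("PhantomScene",
  representation(
    reference = "Volume",
    deformed = "Volume",
    meniscusMask = "LabelMask",
    boneMask = "LabelMask",
    truthModel = "WarpModel",
    bonePerturbation = "WarpModel",
    blendWeight = "array",
    inDomain = "array",
    provenance = "list"
  )
)

setValidity("PhantomScene", function(object) {
  m <- object@meniscusMask@data
  b <- object@boneMask@data
  if (!identical(dim(m), dim(b)) ||
    !identical(dim(m), dim(object@reference@data))) {
    return("masks and volumes must share one grid")
  }
  if (any(m & b)) {
    return("meniscus and bone masks must be disjoint")
  }
  if (any(object@blendWeight[b] != 0)) {
    return("truth field must be identically zero inside the bone mask")
  }
  TRUE
})
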