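# Accessor generics and show methods for the core containers.

#' Access the voxel data of a volume-like object
#'
#' @param x a [Volume], [LabelMask] or [PhantomScene].
#' @return the underlying 3D array (numeric for volumes, logical for masks).
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))

#' Voxel spacing in mm
#'
#' @param x a [Volume], [LabelMask] or [DisplacementField].
#' @return numeric(3), per-axis voxel size in mm.
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))

#' Physical origin in mm
#'
#' @param x a [Volume], [LabelMask] or [DisplacementField].
#' @return numeric(3), physical position (mm) of voxel (0, 0, 0).
#' @export
setGeneric("origin", function(x) standardGeneric("origin"))

#' Anatomical axis labels
#'
#' @param x a [Volume].
#' @return character(3), ordered anatomical direction labels.
#' @export
setGeneric("axesLabels", function(x) standardGeneric("axesLabels"))

#' Per-node records of a displacement field
#'
#' @param x a [DisplacementField].
#' @param validOnly return only records with `valid == TRUE`.
#' @return data.frame of per-node records (see [DisplacementField]).
#' @export
setGeneric("records", function(x, validOnly = FALSE) standardGeneric("records"))

#' @rdname voxelData
#' @export
setMethod("voxelData", "Volume", function(x) x@data)

#' @rdname voxelData
#' @export
setMethod("voxelData", "LabelMask", function(x) x@data)

#' @rdname spacing
#' @export
setMethod("spacing", "Volume", function(x) x@spacing)

#' @rdname spacing
#' @export
setMethod("spacing", "LabelMask", function(x) x@spacing)

#' @rdname spacing
#' @export
setMethod("spacing", "DisplacementField", function(x) x@spacing)

#' @rdname origin
#' @export
setMethod("origin", "Volume", function(x) x@origin)

#' @rdname origin
#' @export
setMethod("origin", "LabelMask", function(x) x@origin)

#' @rdname origin
#' @export
setMethod("origin", "DisplacementField", function(x) x@origin)

#' @rdname axesLabels
#' @export
setMethod("axesLabels", "Volume", function(x) x@axes)

#' @rdname records
#' @export
setMethod("records", "DisplacementField", function(x, validOnly = FALSE) {
  r <- x@records
  if (validOnly) r[r$valid, , drop = FALSE] else r
})

setMethod("show", "Volume", function(object) {
  d <- dim(object@data)
  cat(
    "Volume:", paste(d, collapse = " x "), "voxels,",
    paste(format(object@spacing, digits = 4), collapse = " x "), "mm\n"
  )
  cat("  axes:", paste(object@axes, collapse = ", "), "\n")
  cat(
    "  origin (mm):", paste(format(object@origin, digits = 4), collapse = ", "),
    " intensity range:",
    paste(format(range(object@data), digits = 4), collapse = " .. "), "\n"
  )
})

setMethod("show", "LabelMask", function(object) {
  d <- dim(object@data)
  cat(
    "LabelMask:", paste(d, collapse = " x "), "voxels,",
    sum(object@data), "foreground\n"
  )
})

setMethod("show", "DVCConfig", function(object) {
  cat(
    "DVCConfig: subset", 2L * object@subsetHalfWidth + 1L, "^3 (h =",
    object@subsetHalfWidth, "), grid step", object@gridStep,
    ", search radius", object@searchRadius, "\n"
  )
  cat(
    "  shape order", object@shapeOrder, ", correlation floor",
    object@correlationFloor, ", tol", object@tol, ", max iter",
    object@maxIter, ", prefilter sigma", object@prefilterSigma, "\n"
  )
})

setMethod("show", "DisplacementField", function(object) {
  r <- object@records
  cat(
    "DisplacementField:", nrow(r), "nodes (", sum(r$valid), "valid ), grid step",
    object@gridStep, "voxels\n"
  )
  if (any(r$valid)) {
    v <- r[r$valid, ]
    cat(
      "  mean |u| =",
      format(mean(sqrt(v$ux_vox^2 + v$uy_vox^2 + v$uz_vox^2)), digits = 4),
      "voxels; mean ZNCC =", format(mean(v$correlation), digits = 4), "\n"
    )
  }
})

setMethod("show", "RigidTransform", function(object) {
  cat(
    "RigidTransform: rotation (deg)",
    paste(format(object@rotation, digits = 4), collapse = ", "),
    "; translation (mm)",
    paste(format(object@translation, digits = 4), collapse = ", "), "\n"
  )
  cat(
    "  center (mm):", paste(format(object@center, digits = 4), collapse = ", "),
    if (!is.na(object@correlation)) {
      paste("; metric NCC:", format(object@correlation, digits = 4))
    } else {
      ""
    }, "\n"
  )
  if (!object@metricOk) cat("  [flagged: metric below configured floor]\n")
})

setMethod("show", "WarpModel", function(object) {
  cat("WarpModel:", object@kind, "\n")
  if (object@kind == "composite") {
    cat("  ", length(object@params$models), "component models\n")
  }
})

setMethod("show", "PhantomScene", function(object) {
  cat("PhantomScene:\n  ")
  show(object@reference)
  cat(
    "  meniscus voxels:", sum(object@meniscusMask@data),
    "; bone voxels:", sum(object@boneMask@data), "\n"
  )
  cat("  truth model:", object@truthModel@kind, "\n")
})
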