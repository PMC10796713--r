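# Volume and mask construction and NIfTI-1 / CSV input-output.
# All file I/O goes through RNifti (images) and base CSV (tables); the
# voxel geometry carried is spacing (pixdim) and origin (the translation
# column of a diagonal code-2 qform). Axis direction codes beyond that
# are not interpreted.

#' Construct a Volume
#'
#' @param data 3D numeric array of intensities.
#' @param spacing numeric(3), voxel size per axis in mm.
#' @param origin numeric(3), physical position (mm) of voxel (0,0,0).
#' @param axes character(3), anatomical direction labels.
#' @return a [Volume].
#' @examples
#' v <- Volume(array(seq_len(8^3), c(8, 8, 8)), spacing = c(0.35, 0.35, 0.35))
#' spacing(v)
#' @export
Volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                   axes = c("lateromedial", "anteroposterior", "axial")) {
  new("Volume",
    data = data, spacing = as.numeric(spacing),
    origin = as.numeric(origin), axes = as.character(axes)
  )
}

#' Construct a LabelMask
#'
#' @param data 3D logical (or coercible) array.
#' @param spacing numeric(3), voxel size per axis in mm.
#' @param origin numeric(3), physical position (mm) of voxel (0,0,0).
#' @return a [LabelMask].
#' @export
LabelMask <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.logical(data)) {
    d <- dim(data)
    data <- array(as.numeric(data) > 0.5, d)
  }
  new("LabelMask",
    data = data, spacing = as.numeric(spacing),
    origin = as.numeric(origin)
  )
}

#' Check that two gridded objects share one voxel geometry
#'
#' Mismatched grids are an error, never silently resampled.
#'
#' @param a,b [Volume] or [LabelMask] objects.
#' @param tol relative tolerance on spacing and origin agreement.
#' @return invisibly TRUE; stops with a diagnostic on mismatch.
#' @export
checkGeometry <- function(a, b, tol = 1e-6) {
  if (!identical(dim(voxelData(a)), dim(voxelData(b)))) {
    stop(
      "geometry mismatch: grid shapes differ (",
      paste(dim(voxelData(a)), collapse = "x"), " vs ",
      paste(dim(voxelData(b)), collapse = "x"), ")"
    )
  }
  if (any(abs(spacing(a) - spacing(b)) > tol * (1 + abs(spacing(a))))) {
    stop("geometry mismatch: voxel spacings differ")
  }
  if (any(abs(origin(a) - origin(b)) > tol * (1 + abs(origin(a))))) {
    stop("geometry mismatch: origins differ")
  }
  invisible(TRUE)
}

.xformMatrix <- function(spacing, origin) {
  m <- diag(c(spacing, 1))
  m[1:3, 4] <- origin
  m
}

#' Read a 3D volume from a NIfTI-1 file
#'
#' Reads a single-component 3D image; voxel spacing is taken from the
#' header pixdim and the origin from the translation column of the stored
#' xform. 4D or multi-component images and non-positive spacings are
#' rejected.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param axes anatomical axis labels to attach (NIfTI-1 carries none of
#'   this study's anatomical naming).
#' @return a [Volume].
#' @seealso [writeVolume()]
#' @export
readVolume <- function(path,
                       axes = c("lateromedial", "anteroposterior", "axial")) {
  if (!file.exists(path)) {
    stop("file not found: ", path)
  }
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L) {
    if (length(d) > 3L && all(d[-(1:3)] == 1L)) {
      img <- array(as.numeric(img), d[1:3])
      d <- d[1:3]
    } else {
      stop("not a 3D volume: ", path, " has dimensions ",
        paste(d, collapse = " x "))
    }
  }
  sp <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(sp)) || any(sp <= 0)) {
    stop("non-positive voxel spacing in ", path)
  }
  xf <- try(RNifti::xform(img), silent = TRUE)
  org <- if (inherits(xf, "try-error")) c(0, 0, 0) else as.numeric(xf[1:3, 4])
  Volume(array(as.numeric(img), d), spacing = sp, origin = org, axes = axes)
}

#' Write a volume to a NIfTI-1 file
#'
#' @param vol a [Volume].
#' @param path output `.nii` or `.nii.gz` path.
#' @param datatype on-disk datatype, `"double"` (lossless round-trip) or
#'   `"float"` (32-bit).
#' @return invisibly, `path`.
#' @seealso [readVolume()]
#' @export
writeVolume <- function(vol, path, datatype = c("double", "float")) {
  datatype <- match.arg(datatype)
  img <- RNifti::asNifti(vol@data)
  RNifti::pixdim(img) <- vol@spacing
  RNifti::`qform<-`(img, structure(.xformMatrix(vol@spacing, vol@origin),
    code = 2L
  )) -> img
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Read a binary mask from a NIfTI-1 file
#'
#' Voxels with intensity > 0.5 become TRUE. When `reference` is supplied
#' the mask geometry is checked against it and any mismatch is an error.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param reference optional companion [Volume].
#' @return a [LabelMask].
#' @export
readLabelMask <- function(path, reference = NULL) {
  v <- readVolume(path)
  m <- LabelMask(v@data > 0.5, spacing = v@spacing, origin = v@origin)
  if (!is.null(reference)) {
    checkGeometry(reference, m)
  }
  m
}

#' Write a mask to a NIfTI-1 file
#'
#' @param mask a [LabelMask].
#' @param path output `.nii` or `.nii.gz` path.
#' @return invisibly, `path`.
#' @export
writeLabelMask <- function(mask, path) {
  v <- Volume(array(as.numeric(mask@data), dim(mask@data)),
    spacing = mask@spacing, origin = mask@origin
  )
  writeVolume(v, path, datatype = "float")
}

# internal constructor shared by correlateVolumes and the tests
displacementField <- function(recs, gridDims, gridOrigin, gridStep,
                              spacing, origin) {
  new("DisplacementField",
    records = recs, gridDims = as.integer(gridDims),
    gridOrigin = as.integer(gridOrigin), gridStep = as.integer(gridStep),
    spacing = as.numeric(spacing), origin = as.numeric(origin)
  )
}

#' Write a displacement field to disk
#'
#' Writes two artifacts under a common prefix: `<prefix>.nii.gz`, a
#' 3-component (4D) 32-bit float NIfTI image on the measurement grid with
#' displacement in mm and NaN at grid positions that are absent or
#' invalid; and `<prefix>.csv`, one row per node with columns
#' `i, j, k, ux_mm, uy_mm, uz_mm, correlation, valid` (0-based node voxel
#' indices, "." decimal).
#'
#' @param field a [DisplacementField].
#' @param prefix output path prefix (extensions are appended).
#' @return invisibly, the two paths written.
#' @seealso [readDisplacementField()]
#' @export
writeDisplacementField <- function(field, prefix) {
  r <- field@records
  gd <- field@gridDims
  arr <- array(NaN, c(gd, 3L))
  gi <- (r$i - field@gridOrigin[1]) %/% field@gridStep + 1L
  gj <- (r$j - field@gridOrigin[2]) %/% field@gridStep + 1L
  gk <- (r$k - field@gridOrigin[3]) %/% field@gridStep + 1L
  keep <- r$valid & !is.na(r$ux_mm)
  arr[cbind(gi, gj, gk, 1L)[keep, , drop = FALSE]] <- r$ux_mm[keep]
  arr[cbind(gi, gj, gk, 2L)[keep, , drop = FALSE]] <- r$uy_mm[keep]
  arr[cbind(gi, gj, gk, 3L)[keep, , drop = FALSE]] <- r$uz_mm[keep]
  niiPath <- paste0(prefix, ".nii.gz")
  csvPath <- paste0(prefix, ".csv")
  img <- RNifti::asNifti(arr)
  gsp <- field@spacing * field@gridStep
  gorg <- field@origin + field@gridOrigin * field@spacing
  RNifti::pixdim(img) <- gsp
  RNifti::`qform<-`(img, structure(.xformMatrix(gsp, gorg), code = 2L)) -> img
  RNifti::writeNifti(img, niiPath, datatype = "float")
  tab <- data.frame(
    i = r$i, j = r$j, k = r$k,
    ux_mm = r$ux_mm, uy_mm = r$uy_mm, uz_mm = r$uz_mm,
    correlation = r$correlation, valid = r$valid
  )
  write.csv(tab, csvPath, row.names = FALSE, quote = FALSE)
  invisible(c(nifti = niiPath, csv = csvPath))
}

#' Read a displacement-field node table
#'
#' Reads the CSV written by [writeDisplacementField()]. When `spacing`
#' is supplied the voxel-unit components are reconstructed as
#' `u_vox = u_mm / spacing`.
#'
#' @param path the `.csv` path (or the prefix it was written under).
#' @param spacing optional numeric(3) voxel size in mm.
#' @return data.frame with the stored columns (plus `ux_vox, uy_vox,
#'   uz_vox` when `spacing` is given).
#' @export
readDisplacementField <- function(path, spacing = NULL) {
  if (!grepl("\\.csv$", path)) {
    path <- paste0(path, ".csv")
  }
  if (!file.exists(path)) {
    stop("file not found: ", path)
  }
  tab <- read.csv(path)
  need <- c("i", "j", "k", "ux_mm", "uy_mm", "uz_mm", "correlation", "valid")
  if (!all(need %in% names(tab))) {
    stop("not a displacement-field table: missing columns")
  }
  tab$valid <- as.logical(tab$valid)
  if (!is.null(spacing)) {
    tab$ux_vox <- tab$ux_mm / spacing[1]
    tab$uy_vox <- tab$uy_mm / spacing[2]
    tab$uz_vox <- tab$uz_mm / spacing[3]
  }
  tab
}
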