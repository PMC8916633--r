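#' CT volume in Hounsfield units
#'
#' Container for a calibrated CT voxel grid. Arrays are stored in the RAS
#' convention: array axis 1 increases toward patient Right is *not* used —
#' axis 1 increases toward Right (+x), axis 2 toward Anterior (+y), axis 3
#' toward Superior (+z). All coordinates are millimetres in patient space;
#' the centre of voxel `(1,1,1)` sits at `origin`.
#'
#' @param voxels 3D numeric array of HU intensities.
#' @param spacing numeric length-3, voxel size per axis in mm (all > 0).
#' @param origin numeric length-3, patient-space position (mm) of voxel (1,1,1).
#' @param kernel reconstruction kernel tag: one of `"standard"`, `"soft"`,
#'   `"bone"`, `"unknown"`.
#' @param scan_id optional identifier carried through the pipeline.
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(voxels, spacing, origin = c(0, 0, 0),
                      kernel = "unknown", scan_id = NULL) {
  stopifnot(is.array(voxels), length(dim(voxels)) == 3L)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three strictly positive values (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be three finite values (mm)")
  if (any(!is.finite(voxels)))
    stop("voxel intensities must be finite HU values")
  kernel <- match.arg(kernel, c("standard", "soft", "bone", "unknown"))
  structure(
    list(voxels = voxels, spacing = spacing, origin = origin,
         orientation = "RAS", kernel = kernel, scan_id = scan_id),
    class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<ct_volume> %d x %d x %d voxels, spacing %s mm, kernel '%s'\n",
              d[1], d[2], d[3],
              paste(format(x$spacing, digits = 3), collapse = " x "),
              x$kernel))
  cat(sprintf("  HU range [%.0f, %.0f], origin (%s) mm, orientation %s\n",
              min(x$voxels), max(x$voxels),
              paste(format(x$origin, digits = 4), collapse = ", "),
              x$orientation))
  invisible(x)
}

#' World coordinates of voxel centres along one axis
#' @param volume a `ct_volume` (or `airway_mask`).
#' @param axis integer 1..3 (x = R, y = A, z = S).
#' @return numeric vector of mm positions.
#' @export
axis_coords <- function(volume, axis) {
  n <- dim(volume$voxels)[axis]
  volume$origin[axis] + (seq_len(n) - 1) * volume$spacing[axis]
}

#' Convert voxel indices to patient-space mm
#' @param volume a `ct_volume` or `airway_mask`.
#' @param index integer vector (i, j, k) or n x 3 matrix of 1-based indices.
#' @return mm coordinates, same shape.
#' @export
voxel_to_world <- function(volume, index) {
  if (is.null(dim(index))) index <- matrix(index, nrow = 1)
  sweep(sweep(index - 1, 2, volume$spacing, "*"), 2, volume$origin, "+")
}

#' Read a CT volume from disk
#'
#' Reads a NIfTI file or a DICOM series directory and returns a [ct_volume]
#' reoriented to RAS. For DICOM the rescale slope/intercept are applied so
#' voxels are in HU, and the reconstruction kernel tag is read from the
#' ConvolutionKernel element when present.
#'
#' @param path file (NIfTI) or directory (DICOM series).
#' @param format `"auto"`, `"nifti"` or `"dicom_series"`.
#' @param scan_id optional identifier attached to the volume.
#' @return A [ct_volume].
#' @export
load_volume <- function(path, format = c("auto", "nifti", "dicom_series"),
                        scan_id = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (dir.exists(path)) "dicom_series" else "nifti"
  }
  if (format == "nifti") {
    if (!file.exists(path)) stop("file not found: ", path)
    img <- RNifti::readNifti(path)
    RNifti::orientation(img) <- "RAS"
    xf <- RNifti::xform(img)
    # require an axis-aligned RAS affine after reorientation
    lin <- unclass(xf)[1:3, 1:3]
    if (max(abs(lin - diag(diag(lin)))) > 1e-4 * max(abs(lin)))
      stop("oblique NIfTI orientations are not supported")
    vox <- array(as.numeric(img), dim = dim(img))
    ct_volume(vox, spacing = diag(lin), origin = unclass(xf)[1:3, 4],
              kernel = "unknown", scan_id = scan_id)
  } else {
    load_dicom_series(path, scan_id = scan_id)
  }
}

#' Write a CT volume (or mask) as NIfTI
#'
#' @param volume a [ct_volume] or `airway_mask`.
#' @param path output `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  vox <- if (inherits(volume, "airway_mask")) volume$voxels * 1 else volume$voxels
  img <- RNifti::asNifti(vox)
  RNifti::pixdim(img) <- volume$spacing
  aff <- diag(4)
  aff[1:3, 1:3] <- diag(volume$spacing)
  aff[1:3, 4] <- volume$origin
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}
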