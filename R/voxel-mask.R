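#' Binary voxel mask with physical geometry
#'
#' A `voxel_mask` is a 3D binary occupancy grid together with its voxel
#' spacing (mm) and origin (mm), the minimal geometry needed to run
#' morphology in voxel space and to report physical volumes. Occupancy must
#' be strictly binary; a valid tumor mask has at least one occupied voxel.
#'
#' @param grid 3D `logical` (or 0/1 numeric) array.
#' @param spacing_mm Numeric length-3, positive voxel spacing in mm.
#' @param origin Numeric length-3 world origin in mm.
#' @return An object of class `voxel_mask` with elements `grid`, `spacing_mm`,
#'   `origin`.
#' @examples
#' g <- array(FALSE, c(5, 5, 5)); g[3, 3, 3] <- TRUE
#' m <- voxel_mask(g)
#' mask_volume_mm3(m)
#' @export
voxel_mask <- function(grid, spacing_mm = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(grid)) != 3L) stop("grid must be a 3D array")
  if (is.numeric(grid)) {
    if (!all(grid %in% c(0, 1))) stop("grid occupancy must be strictly binary")
    grid <- array(grid == 1, dim(grid))
  }
  if (!is.logical(grid)) stop("grid must be logical or 0/1 numeric")
  if (anyNA(grid)) stop("grid must not contain NA")
  stopifnot(length(spacing_mm) == 3L, all(spacing_mm > 0),
            length(origin) == 3L, all(is.finite(origin)))
  structure(list(grid = grid, spacing_mm = as.numeric(spacing_mm),
                 origin = as.numeric(origin)),
            class = "voxel_mask")
}

#' @export
print.voxel_mask <- function(x, ...) {
  cat("<voxel_mask> ", paste(dim(x$grid), collapse = "x"),
      " grid, spacing ", paste(format(x$spacing_mm), collapse = "x"),
      " mm, ", sum(x$grid), " occupied voxels\n", sep = "")
  invisible(x)
}

#' @rdname voxel_mask
#' @param mask A `voxel_mask`.
#' @export
mask_volume_mm3 <- function(mask) {
  stopifnot(inherits(mask, "voxel_mask"))
  sum(mask$grid) * prod(mask$spacing_mm)
}

# Error unless two geometries agree within tol mm.
check_same_geometry <- function(a_dim, a_spacing, a_origin,
                                b_dim, b_spacing, b_origin, tol = 1e-3) {
  if (!identical(as.integer(a_dim), as.integer(b_dim)))
    stop("grid shapes differ")
  if (max(abs(a_spacing - b_spacing)) > tol ||
      max(abs(a_origin - b_origin)) > tol)
    stop("spacing/origin differ beyond ", tol, " mm tolerance")
  invisible(TRUE)
}

#' Read / write masks and volumes as NIfTI-1
#'
#' Thin wrappers around \pkg{RNifti}. `read_mask_nifti()` binarizes at > 0.5
#' and carries spacing from the header; `write_mask_nifti()` writes 0/1
#' voxels, copying the full header (affine included) from `template` when one
#' is given so the output geometry is bit-identical to the input's.
#'
#' @param path File path (`.nii` or `.nii.gz`).
#' @param mask A `voxel_mask`.
#' @param template Optional NIfTI image (or path) whose header is reused.
#' @return `read_mask_nifti()` a `voxel_mask`; `read_volume_nifti()` a list
#'   with `volume` (3D array), `spacing_mm`, `origin`.
#' @export
read_mask_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  voxel_mask(array(as.array(img) > 0.5, dim(img)),
             spacing_mm = RNifti::pixdim(img)[1:3],
             origin = as.numeric(RNifti::origin(img)))
}

#' @rdname read_mask_nifti
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  list(volume = as.array(img), spacing_mm = RNifti::pixdim(img)[1:3],
       origin = as.numeric(RNifti::origin(img)))
}

#' @rdname read_mask_nifti
#' @export
write_mask_nifti <- function(mask, path, template = NULL) {
  stopifnot(inherits(mask, "voxel_mask"))
  arr <- array(as.integer(mask$grid), dim(mask$grid))
  img <- if (is.null(template)) {
    attr(arr, "pixdim") <- mask$spacing_mm
    RNifti::asNifti(arr, datatype = "uint8")
  } else {
    RNifti::asNifti(arr, reference = template, datatype = "uint8")
  }
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname read_mask_nifti
#' @param volume 3D numeric array.
#' @param spacing_mm Voxel spacing for headerless writes.
#' @export
write_volume_nifti <- function(volume, path, spacing_mm = c(1, 1, 1),
                               template = NULL) {
  img <- if (is.null(template)) {
    attr(volume, "pixdim") <- spacing_mm
    RNifti::asNifti(volume)
  } else {
    RNifti::asNifti(volume, reference = template)
  }
  RNifti::writeNifti(img, path)
  invisible(path)
}
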