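#' SUV volume container
#'
#' A 3-D grid of body-weight-normalized Standardized Uptake Values (SUV,
#' g/mL) together with the physical voxel spacing in mm and a timepoint
#' label. This is the common currency of the pipeline: phantom generation,
#' segmentation and every feature extractor consume or produce it.
#'
#' @param values numeric 3-D array of SUV, all values >= 0.
#' @param spacing numeric length-3 vector of voxel edge lengths in mm.
#' @param timepoint `"baseline"` or `"post_cht"`.
#' @return An object of class `suv_volume`: a list with elements `values`,
#'   `spacing`, `timepoint`.
#' @examples
#' vol <- suv_volume(array(1, c(4, 4, 4)), spacing = c(2, 2, 2))
#' dim(vol$values)
#' @export
suv_volume <- function(values, spacing, timepoint = c("baseline", "post_cht")) {
  timepoint <- match.arg(timepoint)
  values <- as.array(values)
  if (length(dim(values)) != 3L) stopf("`values` must be a 3-D array")
  if (any(dim(values) < 1L)) stopf("grid must have >= 1 voxel per axis")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stopf("`spacing` must be 3 positive voxel edge lengths in mm")
  }
  if (any(values < 0, na.rm = TRUE)) stopf("SUV values must be non-negative")
  structure(list(values = values, spacing = spacing, timepoint = timepoint),
            class = "suv_volume")
}

#' Lesion mask container
#'
#' A binary volume of interest (VOI) aligned with a companion [suv_volume()]:
#' same grid dimensions, same spacing. Foreground voxels define the lesion.
#'
#' @param values logical/0-1 numeric 3-D array.
#' @param spacing numeric length-3 voxel spacing in mm, identical to the
#'   companion volume's.
#' @return An object of class `lesion_mask` with elements `values` (logical
#'   array) and `spacing`.
#' @export
lesion_mask <- function(values, spacing) {
  values <- as.array(values)
  if (length(dim(values)) != 3L) stopf("`values` must be a 3-D array")
  if (is.numeric(values)) {
    if (any(!values %in% c(0, 1))) stopf("mask values must be binary")
    values <- array(values > 0, dim(values))
  }
  if (!is.logical(values)) stopf("mask values must be logical or 0/1")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0)) {
    stopf("`spacing` must be 3 positive voxel edge lengths in mm")
  }
  structure(list(values = values, spacing = spacing), class = "lesion_mask")
}

check_aligned <- function(vol, mask) {
  if (!identical(dim(vol$values), dim(mask$values))) {
    stopf("mask/image dimension mismatch: %s vs %s",
          paste(dim(mask$values), collapse = "x"),
          paste(dim(vol$values), collapse = "x"))
  }
  if (max(abs(vol$spacing - mask$spacing)) > 1e-9) {
    stopf("mask and image voxel spacing differ")
  }
  invisible(TRUE)
}

check_nonempty <- function(mask) {
  if (!any(mask$values)) stopf("empty mask")
  invisible(TRUE)
}

#' Voxel volume in mm^3
#' @param x a `suv_volume` or `lesion_mask`.
#' @return scalar voxel volume in mm^3.
#' @export
voxel_volume <- function(x) prod(x$spacing)

# Physical voxel-center coordinates (mm) of the foreground voxels, n x 3.
mask_centers_mm <- function(mask) {
  ijk <- which(mask$values, arr.ind = TRUE)
  sweep(ijk - 0.5, 2L, mask$spacing, "*")
}

#' Read and write SUV volumes and masks as NIfTI
#'
#' Thin wrappers over RNifti keeping the spacing metadata (`pixdim`) in step
#' with the in-memory containers. Masks are stored as 0/1 integer volumes.
#'
#' @param path NIfTI file path (`.nii` or `.nii.gz`).
#' @param timepoint timepoint label attached to the volume on read.
#' @return `read_suv_volume` a [suv_volume()]; `read_lesion_mask` a
#'   [lesion_mask()]; the writers return `path` invisibly.
#' @export
read_suv_volume <- function(path, timepoint = c("baseline", "post_cht")) {
  timepoint <- match.arg(timepoint)
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(sp)) || any(sp <= 0)) {
    stopf("missing or invalid voxel spacing metadata in %s", path)
  }
  suv_volume(array(as.numeric(img), dim(img)[1:3]), sp, timepoint)
}

#' @rdname read_suv_volume
#' @param vol a [suv_volume()] to write.
#' @export
write_suv_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$values)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname read_suv_volume
#' @export
read_lesion_mask <- function(path) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(sp)) || any(sp <= 0)) {
    stopf("missing or invalid voxel spacing metadata in %s", path)
  }
  lesion_mask(array(as.numeric(img) > 0.5, dim(img)[1:3]), sp)
}

#' @rdname read_suv_volume
#' @param mask a [lesion_mask()] to write.
#' @export
write_lesion_mask <- function(mask, path) {
  img <- RNifti::asNifti(array(as.integer(mask$values), dim(mask$values)))
  RNifti::pixdim(img) <- mask$spacing
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' @export
print.suv_volume <- function(x, ...) {
  cat(sprintf("<suv_volume> %s, %s voxels, spacing %s mm, SUV range [%.3g, %.3g]\n",
              x$timepoint, paste(dim(x$values), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.lesion_mask <- function(x, ...) {
  cat(sprintf("<lesion_mask> %s voxels, %d foreground, spacing %s mm\n",
              paste(dim(x$values), collapse = "x"), sum(x$values),
              paste(format(x$spacing), collapse = "x")))
  invisible(x)
}
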