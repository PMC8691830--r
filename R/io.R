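# NIfTI input/output for image series and parameter maps.

#' Write an image series to NIfTI
#'
#' The voxel size is stored in the spatial pixdim fields and the frame time
#' in the temporal one.  The brain mask is written alongside as
#' `<path>_mask.nii.gz` and the infusion onset, when known, into the
#' header description.
#'
#' @param series An [image_series()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_series_nifti <- function(series, path) {
  stopifnot(inherits(series, "image_series"))
  img <- RNifti::asNifti(series$data)
  RNifti::pixdim(img) <- c(series$voxel_size, series$frame_time)
  if (!is.null(series$onset))
    img$descrip <- sprintf("onset=%g", series$onset)
  RNifti::writeNifti(img, path)
  mask_path <- sub("(\\.nii(\\.gz)?)$", "_mask\\1", path)
  msk <- RNifti::asNifti(series$brain_mask * 1L)
  RNifti::pixdim(msk) <- series$voxel_size
  RNifti::writeNifti(msk, mask_path)
  invisible(path)
}

#' Read an image series from NIfTI
#'
#' @param path NIfTI path written by [write_series_nifti()].
#' @return An [image_series()].
#' @export
read_series_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  hdr <- RNifti::niftiHeader(img)
  onset <- NULL
  m <- regmatches(hdr$descrip, regexec("onset=([0-9.eE+-]+)", hdr$descrip))[[1]]
  if (length(m) == 2) onset <- as.numeric(m[2])
  mask_path <- sub("(\\.nii(\\.gz)?)$", "_mask\\1", path)
  mask <- NULL
  if (file.exists(mask_path)) {
    mask <- array(as.logical(RNifti::readNifti(mask_path) > 0),
                  dim(img)[1:3])
  }
  image_series(array(as.numeric(img), dim(img)),
               frame_time = if (length(pd) >= 4) pd[4] else 1,
               voxel_size = pd[1:3], onset = onset, brain_mask = mask)
}

#' Write a 3D parameter map to NIfTI
#'
#' @param map Numeric 3D array.
#' @param path Output path.
#' @param voxel_size Length-3 voxel size (mm).
#' @return `path`, invisibly.
#' @export
write_map_nifti <- function(map, path, voxel_size = c(1, 1, 1)) {
  stopifnot(is.array(map), length(dim(map)) == 3L)
  img <- RNifti::asNifti(map)
  RNifti::pixdim(img) <- voxel_size
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a 3D parameter map from NIfTI
#'
#' @param path NIfTI path.
#' @return Numeric 3D array.
#' @export
read_map_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 2L) d <- c(d, 1L)  # NIfTI drops trailing singleton dims
  array(as.numeric(img), d)
}
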