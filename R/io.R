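#' Read and write CT volumes
#'
#' Volumes are stored either as NIfTI-1 (one `.nii`/`.nii.gz` file; voxel
#' dimensions carry pixel spacing and the scanning interval) or as a minimal
#' DICOM series (one Explicit-VR-Little-Endian file per slice; geometry and
#' pixel-module subset only). `read_volume()` orders slices by ascending
#' position along the slice axis regardless of filename order, clips stored
#' values into `[0, 4095]`, and fails — rather than guessing — when geometry
#' metadata is missing or inconsistent across a series.
#'
#' @param path file path (NIfTI) or directory (DICOM series).
#' @param format `"nifti"` or `"dicom_series"`. For `read_volume` the default
#'   `"auto"` infers the format from the path.
#' @param volume a [ct_volume].
#' @return `read_volume`: a [ct_volume]. `write_volume`: the path, invisibly.
#' @export
read_volume <- function(path, format = c("auto", "nifti", "dicom_series")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (dir.exists(path)) "dicom_series" else "nifti"
  if (format == "nifti") read_volume_nifti(path) else read_volume_dicom(path)
}

#' @rdname read_volume
#' @export
write_volume <- function(volume, path, format = c("nifti", "dicom_series")) {
  format <- match.arg(format)
  stopifnot(inherits(volume, "ct_volume"))
  if (format == "nifti") write_volume_nifti(volume, path)
  else write_volume_dicom(volume, path)
  invisible(path)
}

read_volume_nifti <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  img <- RNifti::readNifti(path)
  pd <- attr(img, "pixdim") %||% RNifti::pixdim(img)
  if (length(pd) < 3 || any(!is.finite(pd[1:3])) || any(pd[1:3] <= 0))
    stopf("NIfTI %s lacks usable voxel dimensions", path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L) stopf("expected a 3-D NIfTI, got %d-D", length(dim(arr)))
  vox <- clip(round_half_away(aperm(arr, c(3, 2, 1))), 0, 4095)
  ct_volume(vox, thickness = pd[3], interval = pd[3],
            pixel_spacing = c(pd[2], pd[1]), source = path)
}

write_volume_nifti <- function(volume, path) {
  # NIfTI axes are (x = cols, y = rows, z = slices)
  arr <- aperm(volume$voxels, c(3, 2, 1))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(volume$pixel_spacing[2], volume$pixel_spacing[1],
                           volume$interval)
  RNifti::writeNifti(img, path, datatype = "int16")
}

#' Export one slice as an 8-bit PNG
#'
#' Renders a stored-value slice through a window/level transform (defaults
#' show the full 12-bit range) for quick visual inspection.
#'
#' @param volume a [ct_volume].
#' @param slice 1-based slice index.
#' @param path output `.png` path.
#' @param center,width window center and width in stored values.
#' @export
write_slice_png <- function(volume, slice, path, center = 2048, width = 4096) {
  x <- get_slice(volume, slice)
  g <- clip((x - (center - width / 2)) / width, 0, 1)
  png::writePNG(g, path)
  invisible(path)
}
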