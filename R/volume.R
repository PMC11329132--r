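#' CT volume container
#'
#' A `ct_volume` is a 3-D stack of integer stored-value slices together with
#' its acquisition geometry. Stored values are 12-bit CT pixel values in
#' `[0, 4095]`; they relate to Hounsfield units through the (metadata-only)
#' rescale intercept. Slice index 1 is the lowest position along the slice
#' axis; for volumes handled here the scanning interval equals the slice
#' thickness.
#'
#' @param voxels integer-valued 3-D array, `slices x rows x cols`, all values
#'   in `[0, 4095]`.
#' @param thickness slice thickness in mm (> 0).
#' @param interval scanning interval in mm; defaults to `thickness`.
#' @param pixel_spacing length-2 numeric, in-plane spacing (row, col) in mm.
#' @param intercept rescale intercept in HU (metadata only; default -1024).
#' @param source free-text source identifier.
#' @return an object of class `ct_volume`.
#' @export
ct_volume <- function(voxels, thickness, interval = thickness,
                      pixel_spacing = c(0.5, 0.5), intercept = -1024,
                      source = "") {
  if (length(dim(voxels)) != 3L)
    stopf("voxels must be a 3-D array (slices x rows x cols)")
  if (any(dim(voxels) <= 0L)) stopf("voxel array has a non-positive dimension")
  if (anyNA(voxels)) stopf("voxel array contains NA")
  rng <- range(voxels)
  if (rng[1] < 0 || rng[2] > 4095)
    stopf("stored values outside [0, 4095]: range %s..%s", rng[1], rng[2])
  if (any(voxels != trunc(voxels)))
    stopf("stored values must be integers")
  if (!isTRUE(thickness > 0) || !isTRUE(interval > 0))
    stopf("thickness and interval must be positive")
  if (length(pixel_spacing) != 2L || any(pixel_spacing <= 0))
    stopf("pixel_spacing must be two positive numbers")
  structure(list(voxels = voxels, thickness = thickness, interval = interval,
                 pixel_spacing = as.numeric(pixel_spacing),
                 intercept = intercept, source = as.character(source)),
            class = "ct_volume")
}

#' @exportS3Method base::print
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<ct_volume> %d slices x %d x %d, thickness %g mm, interval %g mm, spacing %g x %g mm\n",
              d[1], d[2], d[3], x$thickness, x$interval,
              x$pixel_spacing[1], x$pixel_spacing[2]))
  cat(sprintf("  stored values %d..%d, intercept %g HU%s\n",
              min(x$voxels), max(x$voxels), x$intercept,
              if (nzchar(x$source)) paste0(", source: ", x$source) else ""))
  invisible(x)
}

#' @export
dim.ct_volume <- function(x) dim(x$voxels)

n_slices <- function(vol) dim(vol$voxels)[1]

get_slice <- function(vol, i) vol$voxels[i, , ]

#' Normalized image
#'
#' A 2-D real-valued image tagged with its scale convention: `"signed_unit"`
#' for values in `[-1, 1]` (the generator's input/output scale) or `"unit"`
#' for `[0, 1]` (the scale on which residuals are added and metrics are
#' computed).
#'
#' @param values numeric matrix.
#' @param scale `"signed_unit"` or `"unit"`.
#' @export
normalized_image <- function(values, scale = c("signed_unit", "unit")) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  lim <- if (scale == "signed_unit") c(-1, 1) else c(0, 1)
  if (min(values) < lim[1] - 1e-12 || max(values) > lim[2] + 1e-12)
    stopf("values outside the %s range [%g, %g]", scale, lim[1], lim[2])
  structure(values, scale = scale, class = c("normalized_image", "matrix", "array"))
}

img_scale <- function(img) attr(img, "scale")

# plain numeric matrix from a normalized_image (drops class and scale tag)
norm_values <- function(img) {
  m <- unclass(img)
  attr(m, "scale") <- NULL
  m
}

check_stored <- function(x) {
  if (min(x) < 0 || max(x) > 4095)
    stopf("stored values must lie in [0, 4095]")
  invisible(x)
}

#' Scaling between stored values and model ranges
#'
#' `to_signed_unit()` maps stored values `[0, 4095]` affinely onto `[-1, 1]`
#' (`x/2047.5 - 1`, so 0 maps to -1 and 4095 to +1 exactly); this is the scale
#' on which slices enter the generator. `to_unit()` maps onto `[0, 1]`
#' (`x/4095`), the scale on which Method 2 adds its residual and all metrics
#' are computed. `from_signed_unit()` inverts the signed map back to integer
#' stored values, clipping first so that mild model overshoot is absorbed:
#' `round(clip((x + 1) * 2047.5, 0, 4095))` with half-away-from-zero rounding.
#' `from_unit()` is the analogue for the unit scale.
#'
#' @param x numeric matrix of stored values (for the `to_` maps) or of
#'   normalized values (for the `from_` maps).
#' @return `to_*`: a [normalized_image]; `from_*`: an integer-valued matrix of
#'   stored values.
#' @examples
#' to_signed_unit(matrix(c(0, 4095), 1))     # -1, +1
#' from_signed_unit(matrix(c(-1, 1.2), 1))   # 0, 4095 (overshoot clipped)
#' @export
to_signed_unit <- function(x) {
  check_stored(x)
  normalized_image(as.matrix(x) / 2047.5 - 1, "signed_unit")
}

#' @rdname to_signed_unit
#' @export
to_unit <- function(x) {
  check_stored(x)
  normalized_image(as.matrix(x) / 4095, "unit")
}

#' @rdname to_signed_unit
#' @export
from_signed_unit <- function(x) {
  m <- round_half_away(clip((norm_values(as.matrix(x)) + 1) * 2047.5, 0, 4095))
  storage.mode(m) <- "integer"
  m
}

#' @rdname to_signed_unit
#' @export
from_unit <- function(x) {
  m <- round_half_away(clip(norm_values(as.matrix(x)) * 4095, 0, 4095))
  storage.mode(m) <- "integer"
  m
}
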