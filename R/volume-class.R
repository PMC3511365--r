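#' Calibrated intensity volume
#'
#' Container for a 3-D microscopy intensity stack with physical calibration.
#' Data are stored as a numeric array indexed `[y, x, z]` (rows are the slow
#' scan axis, one slab per z-plane). Voxel centers sit at
#' `(i - 0.5) * lateral_px_um` laterally and `(k - 0.5) * z_step_um` axially,
#' so the physical extent along an axis is `n * step`.
#'
#' @param data numeric array `[y, x, z]` of nonnegative intensities; a matrix
#'   is promoted to a single-plane volume.
#' @param lateral_px_um lateral pixel size in micrometers per pixel.
#' @param z_step_um axial step between planes in micrometers.
#' @param channel acquisition channel, `"CARS"` or `"autofluorescence"`.
#' @param provenance free-text description of where the volume came from.
#' @return an object of class `VoxelVolume`.
#' @export
voxel_volume <- function(data, lateral_px_um, z_step_um,
                         channel = c("CARS", "autofluorescence"),
                         provenance = "") {
  channel <- match.arg(channel)
  if (is.matrix(data)) dim(data) <- c(dim(data), 1L)
  if (!is.array(data) || length(dim(data)) != 3L)
    .stopf("`data` must be a 3-D array indexed [y, x, z]")
  if (anyNA(data) || any(data < 0))
    .stopf("volume intensities must be finite and nonnegative")
  if (!.is_pos(lateral_px_um) || !.is_pos(z_step_um))
    .stopf("calibration values must be positive")
  structure(
    list(data = data, lateral_px_um = lateral_px_um, z_step_um = z_step_um,
         channel = channel, provenance = provenance),
    class = "VoxelVolume")
}

#' @export
print.VoxelVolume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "VoxelVolume [%s]: %d x %d x %d voxels (%.1f x %.1f x %.1f um), px %.4g um, z-step %.3g um\n",
    x$channel, d[2L], d[1L], d[3L],
    d[2L] * x$lateral_px_um, d[1L] * x$lateral_px_um, d[3L] * x$z_step_um,
    x$lateral_px_um, x$z_step_um))
  cat(sprintf("  intensity range [%.4g, %.4g]  %s\n",
              min(x$data), max(x$data), x$provenance))
  invisible(x)
}

#' Physical extents of a volume
#'
#' @param volume a [voxel_volume()].
#' @return named numeric vector `c(x, y, z)` of extents in micrometers.
#' @export
volume_dims_um <- function(volume) {
  stopifnot(inherits(volume, "VoxelVolume"))
  d <- dim(volume$data)
  c(x = d[2L] * volume$lateral_px_um,
    y = d[1L] * volume$lateral_px_um,
    z = d[3L] * volume$z_step_um)
}

#' Calibrated 2-D image
#'
#' @param data numeric matrix `[y, x]`.
#' @param lateral_px_um lateral pixel size in micrometers per pixel.
#' @param channel source channel label.
#' @return an object of class `LipidImage`.
#' @export
lipid_image <- function(data, lateral_px_um, channel = "CARS") {
  if (!is.matrix(data) || anyNA(data))
    .stopf("`data` must be a numeric matrix without missing values")
  if (!.is_pos(lateral_px_um)) .stopf("`lateral_px_um` must be positive")
  structure(list(data = data, lateral_px_um = lateral_px_um, channel = channel),
            class = "LipidImage")
}

#' @export
print.LipidImage <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("LipidImage [%s]: %d x %d px (%.1f x %.1f um), px %.4g um\n",
              x$channel, d[2L], d[1L], d[2L] * x$lateral_px_um,
              d[1L] * x$lateral_px_um, x$lateral_px_um))
  invisible(x)
}

#' Maximum-intensity z-projection
#'
#' Collapses a stack to the 2-D image on which particle analysis operates:
#' `out[y, x] = max over z of data[y, x, z]`. Lateral calibration is carried
#' through unchanged.
#'
#' @param volume a [voxel_volume()].
#' @return a [lipid_image()].
#' @export
max_project <- function(volume) {
  stopifnot(inherits(volume, "VoxelVolume"))
  d <- dim(volume$data)
  img <- apply(volume$data, c(1L, 2L), max)
  lipid_image(img, volume$lateral_px_um, volume$channel)
}
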