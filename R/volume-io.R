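.sidecar_path <- function(path) sub("\\.tiff?$", ".yaml", path, ignore.case = TRUE)

#' Write a calibrated volume as multi-page TIFF plus YAML sidecar
#'
#' One 16-bit page per z-plane; the sidecar records the physical calibration
#' so that a later [read_volume()] restores the volume exactly. Intensities
#' must be integer counts in `[0, 65535]` (the generator quantizes by
#' default); non-integer data are rounded with a warning.
#'
#' @param volume a [voxel_volume()].
#' @param path output TIFF path; the sidecar is written next to it with a
#'   `.yaml` extension.
#' @param seed optional integer recorded in the sidecar for provenance.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, seed = NULL) {
  stopifnot(inherits(volume, "VoxelVolume"))
  dat <- volume$data
  if (max(dat) > 65535) .stopf("intensities exceed the 16-bit range")
  if (any(dat != round(dat))) {
    .warnf("non-integer intensities rounded to 16-bit counts on write")
    dat <- round(dat)
  }
  pages <- lapply(seq_len(dim(dat)[3L]), function(k) dat[, , k] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none",
                  reduce = FALSE)
  meta <- list(lateral_px_um = volume$lateral_px_um,
               z_step_um = volume$z_step_um,
               channel = volume$channel,
               provenance = volume$provenance)
  if (!is.null(seed)) meta$seed <- as.integer(seed)
  yaml::write_yaml(meta, .sidecar_path(path))
  invisible(path)
}

#' Read a calibrated volume from multi-page TIFF plus YAML sidecar
#'
#' Calibration comes from the sidecar, or from the explicit arguments when no
#' sidecar exists. A stack without any calibration is an error; pixel sizes
#' are never silently assumed.
#'
#' @param path TIFF path.
#' @param lateral_px_um,z_step_um calibration overrides (um), used when the
#'   sidecar is absent.
#' @param channel channel override.
#' @return a [voxel_volume()].
#' @export
read_volume <- function(path, lateral_px_um = NULL, z_step_um = NULL,
                        channel = NULL) {
  if (!file.exists(path)) .stopf("no such file: %s", path)
  sc <- .sidecar_path(path)
  meta <- if (file.exists(sc)) yaml::read_yaml(sc) else list()
  lateral_px_um <- lateral_px_um %||% meta$lateral_px_um
  z_step_um <- z_step_um %||% meta$z_step_um
  if (is.null(lateral_px_um) || is.null(z_step_um))
    .stopf(paste0("missing calibration for %s: no YAML sidecar found and no ",
                  "`lateral_px_um`/`z_step_um` supplied"), path)
  channel <- channel %||% meta$channel %||% "CARS"
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  dims <- vapply(pages, dim, integer(2L))
  if (any(dims[1L, ] != dims[1L, 1L]) || any(dims[2L, ] != dims[2L, 1L]))
    .stopf("ragged TIFF stack: pages differ in size")
  arr <- array(0, c(dims[, 1L], length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- pages[[k]]
  voxel_volume(arr, lateral_px_um, z_step_um, channel = channel,
               provenance = meta$provenance %||% path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
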