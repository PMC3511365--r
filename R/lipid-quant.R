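#' Estimate the background intensity of a volume
#'
#' The background (non-resonant signal plus membrane signal) is the median
#' intensity of voxels at or below the Otsu threshold of the volume's
#' intensity histogram. This is deterministic and robust to the droplet
#' fraction. A constant volume returns that constant with a warning.
#'
#' @param volume a [voxel_volume()].
#' @param method `"otsu_median"` (default) or `"percentile"`.
#' @param percentile background percentile when `method = "percentile"`.
#' @return background intensity (a.u.).
#' @export
estimate_background <- function(volume, method = c("otsu_median", "percentile"),
                                percentile = 0.25) {
  stopifnot(inherits(volume, "VoxelVolume"))
  method <- match.arg(method)
  x <- as.vector(volume$data)
  if (diff(range(x)) == 0) {
    .warnf("constant volume: background equals the single intensity value")
    return(x[1L])
  }
  if (method == "percentile")
    return(unname(stats::quantile(x, percentile)))
  thr <- .otsu_threshold(x)
  median(x[x <= thr])
}

#' CARS-intensity lipid content of a volume
#'
#' Implements the intensity route to liver lipid content: the mean CARS
#' voxel intensity is background-corrected (clipped at zero) and
#' square-rooted. Because the resonant CARS signal grows with the square of
#' the C-H oscillator concentration, the square root restores a score that
#' is linear in lipid concentration.
#'
#' @param volume a [voxel_volume()].
#' @param background background intensity (a.u., `>= 0`); typically from
#'   [estimate_background()].
#' @param volume_id identifier carried into reports.
#' @param group group label (e.g. treatment arm).
#' @return a one-row `data.frame` of class `LipidQuantResult` with columns
#'   `volume_id`, `group`, `mean_intensity`, `background`, `corrected`,
#'   `level` (`= sqrt(corrected)`) and `normalized_level` (`NA` until
#'   [normalize_levels()] is applied).
#' @export
lipid_level <- function(volume, background = estimate_background(volume),
                        volume_id = "volume", group = NA_character_) {
  stopifnot(inherits(volume, "VoxelVolume"))
  if (!is.numeric(background) || length(background) != 1L || background < 0)
    .stopf("`background` must be a single nonnegative intensity")
  m <- mean(volume$data)
  corrected <- max(m - background, 0)
  res <- data.frame(volume_id = volume_id, group = group,
                    mean_intensity = m, background = background,
                    corrected = corrected, level = sqrt(corrected),
                    normalized_level = NA_real_,
                    stringsAsFactors = FALSE)
  class(res) <- c("LipidQuantResult", class(res))
  res
}

#' Normalize lipid levels to a reference group
#'
#' Divides every `level` by the mean level of the reference group, so the
#' reference group averages exactly 1 and other groups read as fold changes.
#'
#' @param results a `data.frame` of stacked [lipid_level()] rows.
#' @param reference_group label of the reference group.
#' @return `results` with `normalized_level` filled in.
#' @export
normalize_levels <- function(results, reference_group) {
  if (!is.data.frame(results) || nrow(results) == 0L)
    .stopf("`results` must be a non-empty data.frame of lipid levels")
  ref <- results$level[results$group %in% reference_group]
  if (length(ref) == 0L)
    .stopf("reference group '%s' is empty", reference_group)
  ref_mean <- mean(ref)
  if (ref_mean == 0)
    .stopf("reference group '%s' has zero mean level", reference_group)
  results$normalized_level <- results$level / ref_mean
  results
}
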