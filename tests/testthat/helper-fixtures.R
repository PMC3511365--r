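# fixtures are generated in code; nothing is stored on disk

# a small, fast volume spec for unit tests (full presets are reserved for
# the acceptance suite)
small_spec <- function(...) {
  args <- list(...)
  defaults <- list(dims_um = c(40, 40, 10), lateral_px_um = 40 / 128,
                   n_droplets = 8, radius_median_um = 0.8,
                   radius_sigma = 0.2, seed = 1L)
  do.call(volume_spec, utils::modifyList(defaults, args))
}

# rasterize bright discs on a flat background; pixel centers at
# (i - 0.5) * px. Returns a LipidImage.
disc_image <- function(centers_um, diam_um, px = 0.1, field_um = NULL,
                       bg = 10, value = 100) {
  field_um <- field_um %||% (max(centers_um) + max(diam_um))
  n <- round(field_um / px)
  img <- matrix(bg, n, n)
  xc <- (seq_len(n) - 0.5) * px
  for (i in seq_len(nrow(centers_um))) {
    r <- diam_um[i] / 2
    dx2 <- (xc - centers_um[i, 1L])^2
    dy2 <- (xc - centers_um[i, 2L])^2
    img[outer(dy2, dx2, "+") <= r^2] <- value
  }
  lipid_image(img, px)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# lay diameters out on a square lattice with enough spacing to keep discs
# separate, returning the image and the true diameters in order
disc_lattice <- function(diams_um, px = 0.1, spacing_um = 8) {
  k <- ceiling(sqrt(length(diams_um)))
  pos <- (seq_len(k) - 0.5) * spacing_um
  centers <- as.matrix(expand.grid(x = pos, y = pos))[seq_along(diams_um), ,
                                                      drop = FALSE]
  disc_image(centers, diams_um, px = px, field_um = k * spacing_um)
}

# closed-form band height of a noiseless BandSpec profile, measured with the
# same local-linear-baseline definition but on a dense independent grid
closed_form_height <- function(spec, center, half_window = 15) {
  nu <- seq(center - half_window, center + half_window, by = 0.01)
  y <- band_profile(spec, nu)
  base <- y[1L] + (y[length(y)] - y[1L]) * (nu - nu[1L]) / (nu[length(nu)] - nu[1L])
  max(y - base)
}

# construct a DropletSegmentation object directly (white-box fixture for
# grading logic; areas in um^2)
manual_seg <- function(kept_areas, rejected_areas = numeric(),
                       rejected_reason = character(), field_area_um2 = 1000,
                       px = 0.2) {
  eq <- function(a) 2 * sqrt(a / pi)
  structure(list(
    records = data.frame(label = seq_along(kept_areas),
                         x_um = seq_along(kept_areas),
                         y_um = seq_along(kept_areas),
                         area_um2 = kept_areas,
                         equiv_diameter_um = eq(kept_areas),
                         mean_intensity = rep(100, length(kept_areas))),
    rejected = data.frame(label = length(kept_areas) + seq_along(rejected_areas),
                          area_um2 = rejected_areas,
                          equiv_diameter_um = eq(rejected_areas),
                          reason = rejected_reason),
    n_components = length(kept_areas) + length(rejected_areas),
    threshold = 50, background = 40, field_area_um2 = field_area_um2,
    lateral_px_um = px, d_min = 0.4, d_max = 5, mask = NULL),
    class = "DropletSegmentation")
}

manual_quant <- function(level = 1, normalized = 1, id = "volume",
                         group = "g") {
  res <- data.frame(volume_id = id, group = group, mean_intensity = 50,
                    background = 40, corrected = level^2, level = level,
                    normalized_level = normalized, stringsAsFactors = FALSE)
  class(res) <- c("LipidQuantResult", class(res))
  res
}
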