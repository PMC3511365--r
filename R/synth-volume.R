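#' Specification of a synthetic CARS liver volume
#'
#' Describes the simulated tissue and imaging model from which
#' [generate_volume()] draws: spherical lipid droplets with lognormal radii
#' placed in a calibrated volume, a smooth bounded membrane-background
#' texture, quadratic resonant contrast (CARS signal proportional to the
#' square of the local lipid concentration), an anisotropic Gaussian PSF,
#' additive Gaussian detector noise, and 16-bit quantization.
#'
#' @param dims_um numeric length-3, physical extents (x, y, z) in
#'   micrometers. Default is the standard liver analysis volume
#'   167 x 167 x 25 um.
#' @param lateral_px_um lateral pixel size (um/px); the default samples the
#'   167 um field with 512 pixels.
#' @param z_step_um axial step (um) between planes.
#' @param n_droplets number of lipid droplets to place.
#' @param radius_median_um,radius_sigma lognormal radius distribution
#'   (median in um, log-sd); radii are hard-clipped to
#'   `[r_min_um, r_max_um]`.
#' @param r_min_um,r_max_um radius clip bounds (um); `r_min_um` may not be
#'   smaller than the lateral pixel size.
#' @param droplet_conc per-droplet lipid concentration (a.u.).
#' @param k_cars resonant contrast constant: droplet intensity is
#'   `k_cars * concentration^2`.
#' @param membrane_bg mean background intensity from cellular membranes
#'   (a.u.).
#' @param membrane_amp relative amplitude of the membrane texture; the
#'   texture is a smoothed random field squashed through `tanh`, so it is
#'   bounded in `membrane_bg * (1 +/- membrane_amp)`. Set to 0 to disable
#'   the texture (flat membrane background).
#' @param membrane_scale_um correlation length of the membrane texture (um).
#' @param nonres_bg additive non-resonant background offset (a.u.).
#' @param noise_sd additive Gaussian noise standard deviation (a.u.).
#' @param psf_sigma_um Gaussian PSF sigmas, `c(lateral, axial)` in um.
#' @param autofluor_fraction fraction of droplets flagged as belonging to
#'   lipid-rich non-parenchymal cells; when positive, a second
#'   autofluorescence channel is simulated.
#' @param min_gap_um minimum in-plane gap between droplet boundaries when
#'   `overlap = FALSE`; guarantees droplets remain separated in the
#'   z-projection.
#' @param overlap if `TRUE`, droplet centers are placed independently so
#'   droplets may overlap or merge in projection (stresses the
#'   merged-particle rejection path).
#' @param quantize round intensities to integer counts (16-bit detector
#'   model); required for exact TIFF round-trips.
#' @param seed integer seed; identical specs generate bit-identical output.
#' @return an object of class `VolumeSpec`.
#' @export
volume_spec <- function(dims_um = c(167, 167, 25),
                        lateral_px_um = 167 / 512,
                        z_step_um = 1,
                        n_droplets = 50,
                        radius_median_um = 0.65,
                        radius_sigma = 0.25,
                        r_min_um = 0.5,
                        r_max_um = 2.0,
                        droplet_conc = 20,
                        k_cars = 1,
                        membrane_bg = 30,
                        membrane_amp = 0.15,
                        membrane_scale_um = 2,
                        nonres_bg = 10,
                        noise_sd = 2,
                        psf_sigma_um = c(0.2, 0.75),
                        autofluor_fraction = 0,
                        min_gap_um = 1.2,
                        overlap = FALSE,
                        quantize = TRUE,
                        seed = 1L) {
  spec <- list(dims_um = dims_um, lateral_px_um = lateral_px_um,
               z_step_um = z_step_um, n_droplets = n_droplets,
               radius_median_um = radius_median_um,
               radius_sigma = radius_sigma,
               r_min_um = r_min_um, r_max_um = r_max_um,
               droplet_conc = droplet_conc, k_cars = k_cars,
               membrane_bg = membrane_bg, membrane_amp = membrane_amp,
               membrane_scale_um = membrane_scale_um, nonres_bg = nonres_bg,
               noise_sd = noise_sd, psf_sigma_um = psf_sigma_um,
               autofluor_fraction = autofluor_fraction,
               min_gap_um = min_gap_um, overlap = isTRUE(overlap),
               quantize = isTRUE(quantize), seed = as.integer(seed),
               group = NA_character_, mean_area_um2 = NA_real_)
  class(spec) <- "VolumeSpec"
  validate_volume_spec(spec)
  spec
}

validate_volume_spec <- function(spec) {
  with(spec, {
    if (length(dims_um) != 3L || !.is_pos(dims_um))
      .stopf("`dims_um` must be three positive extents (x, y, z)")
    if (!.is_pos(lateral_px_um) || !.is_pos(z_step_um))
      .stopf("pixel sizes must be positive")
    if (!.is_count(n_droplets)) .stopf("`n_droplets` must be a count")
    if (!.is_pos(radius_median_um) || !.is_pos(radius_sigma))
      .stopf("radius distribution parameters must be positive")
    if (r_min_um < lateral_px_um)
      .stopf("`r_min_um` (%.3g) may not be below the lateral pixel size (%.3g)",
             r_min_um, lateral_px_um)
    if (r_max_um <= r_min_um) .stopf("`r_max_um` must exceed `r_min_um`")
    if (2 * r_max_um >= min(dims_um))
      .stopf("largest droplet does not fit in the volume")
    if (!.is_pos(droplet_conc) || !.is_pos(k_cars))
      .stopf("`droplet_conc` and `k_cars` must be positive")
    if (membrane_bg < 0 || nonres_bg < 0 || noise_sd < 0 ||
        membrane_amp < 0 || membrane_amp >= 1)
      .stopf("backgrounds and noise must be nonnegative, membrane_amp in [0, 1)")
    if (length(psf_sigma_um) != 2L || any(psf_sigma_um < 0))
      .stopf("`psf_sigma_um` must be c(lateral, axial) >= 0")
    if (autofluor_fraction < 0 || autofluor_fraction > 1)
      .stopf("`autofluor_fraction` must be in [0, 1]")
    if (min_gap_um < 0) .stopf("`min_gap_um` must be nonnegative")
  })
  invisible(spec)
}

#' @export
print.VolumeSpec <- function(x, ...) {
  cat(sprintf(
    "VolumeSpec%s: %.0f x %.0f x %.0f um, %d droplets (r ~ lognorm(%.3g um, %.2g), clip [%.2g, %.2g])\n",
    if (is.na(x$group)) "" else sprintf(" [%s]", x$group),
    x$dims_um[1L], x$dims_um[2L], x$dims_um[3L], x$n_droplets,
    x$radius_median_um, x$radius_sigma, x$r_min_um, x$r_max_um))
  cat(sprintf(
    "  conc %.3g (k %.3g), membrane %.3g +/- %.0f%%, nonres %.3g, noise sd %.3g, psf (%.2g, %.2g) um, seed %d\n",
    x$droplet_conc, x$k_cars, x$membrane_bg, 100 * x$membrane_amp,
    x$nonres_bg, x$noise_sd, x$psf_sigma_um[1L], x$psf_sigma_um[2L], x$seed))
  invisible(x)
}

# expected squared radius of a clipped lognormal, closed form
.clipped_r2_expectation <- function(median_um, sigma, r_min, r_max) {
  mu <- log(median_um)
  p_lo <- plnorm(r_min, mu, sigma)
  p_hi <- 1 - plnorm(r_max, mu, sigma)
  m2 <- exp(2 * mu + 2 * sigma^2)
  # E[r^2; r_min < r < r_max] via the lognormal partial expectation
  z <- function(r) (log(r) - mu - 2 * sigma^2) / sigma
  mid <- m2 * (stats::pnorm(z(r_max)) - stats::pnorm(z(r_min)))
  r_min^2 * p_lo + mid + r_max^2 * p_hi
}

# solve the lognormal median so that the expected projected disc area
# E[pi r^2] (after clipping) hits the target
.calibrate_radius_median <- function(target_area_um2, sigma, r_min, r_max) {
  f <- function(m) pi * .clipped_r2_expectation(m, sigma, r_min, r_max) -
    target_area_um2
  uniroot(f, c(r_min / 2, r_max * 2), tol = 1e-8)$root
}

#' Steatosis-severity presets for cohort simulation
#'
#' Maps a severity group to the droplet burden observed in the three animal
#' groups the pipeline is calibrated against: per standard analysis volume
#' (167 x 167 x 25 um), about 50 droplets of mean projected area 1.5 um^2
#' (`control`, no steatosis), 300 of 6.6 um^2 (`mild`), and 800 of 10.2 um^2
#' (`severe`). The lognormal radius median is solved so the clipped radius
#' distribution reproduces the target mean projected area.
#'
#' @param group one of `"control"`, `"mild"`, `"severe"`.
#' @param ... overrides forwarded to [volume_spec()] (e.g. `noise_sd = 0`,
#'   `overlap = TRUE`, `seed`).
#' @return a `VolumeSpec` carrying the preset, with the group label and the
#'   target mean droplet area recorded.
#' @export
cohort_preset <- function(group = c("control", "mild", "severe"), ...) {
  group <- match.arg(group)
  preset <- switch(group,
    control = list(n = 50L, area = 1.5),
    mild    = list(n = 300L, area = 6.6),
    severe  = list(n = 800L, area = 10.2))
  args <- list(...)
  sigma <- if (is.null(args$radius_sigma)) 0.25 else args$radius_sigma
  r_min <- if (is.null(args$r_min_um)) 0.5 else args$r_min_um
  r_max <- if (is.null(args$r_max_um)) 2.0 else args$r_max_um
  med <- .calibrate_radius_median(preset$area, sigma, r_min, r_max)
  args$n_droplets <- preset$n
  args$radius_median_um <- med
  spec <- do.call(volume_spec, args)
  spec$group <- group
  spec$mean_area_um2 <- preset$area
  spec
}

# place droplet centers; when overlap is disallowed the in-plane distance
# between boundaries must exceed min_gap_um, which also forbids 3-D overlap
# and keeps droplets separated in the z-projection
.place_droplets <- function(spec, radii) {
  n <- length(radii)
  dims <- spec$dims_um
  xs <- ys <- zs <- numeric(n)
  if (n == 0L) return(data.frame(x_um = xs, y_um = ys, z_um = zs))
  ord <- order(radii, decreasing = TRUE)   # large droplets first packs better
  radii_o <- radii[ord]
  max_attempts <- max(5000L, 1000L * n)
  attempts <- 0L
  for (i in seq_len(n)) {
    r <- radii_o[i]
    repeat {
      attempts <- attempts + 1L
      if (attempts > max_attempts) {
        dens <- 100 * sum(pi * radii^2) / (dims[1L] * dims[2L])
        .stopf(paste0("could not place %d non-overlapping droplets ",
                      "(projected packing density %.1f%%) within %d attempts; ",
                      "reduce n_droplets or enable `overlap`"),
               n, dens, max_attempts)
      }
      cx <- stats::runif(1, r, dims[1L] - r)
      cy <- stats::runif(1, r, dims[2L] - r)
      cz <- stats::runif(1, r, dims[3L] - r)
      if (spec$overlap || i == 1L) break
      j <- seq_len(i - 1L)
      d2 <- (xs[j] - cx)^2 + (ys[j] - cy)^2
      if (all(d2 >= (radii_o[j] + r + spec$min_gap_um)^2)) break
    }
    xs[i] <- cx; ys[i] <- cy; zs[i] <- cz
  }
  inv <- order(ord)   # restore original draw order
  data.frame(x_um = xs[inv], y_um = ys[inv], z_um = zs[inv])
}

# voxel contributions of one spherical droplet as linear indices + values.
# Lateral inclusion is by pixel center; axially each z-slab receives the
# fraction of the sphere chord it covers (partial-volume weighting), so
# droplets smaller than the z-step still deposit their full signal.
.droplet_voxels <- function(cx, cy, cz, r, value, px, zs, dims) {
  ny <- dims[1L]; nx <- dims[2L]; nz <- dims[3L]
  ix <- max(1L, ceiling((cx - r) / px + 0.5)):min(nx, floor((cx + r) / px + 0.5))
  iy <- max(1L, ceiling((cy - r) / px + 0.5)):min(ny, floor((cy + r) / px + 0.5))
  iz <- max(1L, floor((cz - r) / zs) + 1L):min(nz, ceiling((cz + r) / zs))
  dx2 <- ((ix - 0.5) * px - cx)^2
  dy2 <- ((iy - 0.5) * px - cy)^2
  lat2 <- outer(dy2, dx2, "+")
  h <- sqrt(pmax(r^2 - lat2, 0))          # half chord length at each pixel
  plane_idx <- outer(iy, (ix - 1L) * ny, `+`)
  idx <- integer(0); val <- numeric(0)
  for (k in iz) {
    z0 <- (k - 1L) * zs; z1 <- k * zs
    ov <- pmax(pmin(z1, cz + h) - pmax(z0, cz - h), 0) / zs
    sel <- which(ov > 0)
    if (length(sel) == 0L) next
    idx <- c(idx, plane_idx[sel] + (k - 1L) * ny * nx)
    val <- c(val, value * ov[sel])
  }
  list(idx = idx, val = val)
}

# bounded smooth membrane texture with mean ~1, simulated on a coarse grid
.membrane_texture <- function(dims_px, spec) {
  f <- 4L
  dims_c <- pmax(2L, ceiling(dims_px / f))
  g <- array(rnorm(prod(dims_c)), dims_c)
  sig <- c(spec$membrane_scale_um / spec$lateral_px_um / f,
           spec$membrane_scale_um / spec$lateral_px_um / f,
           spec$membrane_scale_um / spec$z_step_um / f)
  g <- .blur3d(g, sig)
  g <- (g - mean(g)) / max(sd(g), .Machine$double.eps)
  g <- .upsample3d(g, dims_px)
  1 + spec$membrane_amp * tanh(g)
}

#' Generate a synthetic CARS volume with ground truth
#'
#' Draws droplet radii and positions, rasterizes the lipid concentration
#' field, forms the intensity field
#' `nonres_bg + membrane_bg * M + k_cars * conc^2`, convolves it with the
#' anisotropic Gaussian PSF, adds Gaussian noise, and (by default) quantizes
#' to integer detector counts. The returned ground truth records every
#' droplet exactly as placed and is the oracle for all recovery tests.
#'
#' @param spec a [volume_spec()].
#' @return a list of class `SynthVolume` with elements
#'   \describe{
#'     \item{volume}{the CARS [voxel_volume()]}
#'     \item{truth}{a `GroundTruth` object: droplet table, totals, gate
#'       counts, the voxel sums of the pre-PSF concentration field
#'       (`conc_voxel_sum`, proportional to total droplet volume) and of its
#'       square (`conc_sq_voxel_sum`, the quantity the intensity-linearity
#'       oracle predicts the corrected mean intensity from), and the
#'       generating spec}
#'     \item{autofluor}{a second [voxel_volume()] marking droplets of
#'       lipid-rich non-parenchymal cells, or `NULL` when
#'       `autofluor_fraction = 0`}
#'   }
#' @export
generate_volume <- function(spec) {
  validate_volume_spec(spec)
  px <- spec$lateral_px_um
  zs <- spec$z_step_um
  dims_px <- c(round(spec$dims_um[2L] / px),   # y rows
               round(spec$dims_um[1L] / px),   # x cols
               round(spec$dims_um[3L] / zs))   # z planes
  n <- spec$n_droplets
  withr::with_seed(spec$seed, {
    radii <- pmin(pmax(rlnorm(n, log(spec$radius_median_um),
                              spec$radius_sigma),
                       spec$r_min_um), spec$r_max_um)
    npc <- if (spec$autofluor_fraction > 0)
      rbinom(n, 1L, spec$autofluor_fraction) == 1L else rep(FALSE, n)
    centers <- .place_droplets(spec, radii)

    conc <- numeric(prod(dims_px))
    for (i in seq_len(n)) {
      dv <- .droplet_voxels(centers$x_um[i], centers$y_um[i], centers$z_um[i],
                            radii[i], spec$droplet_conc, px, zs, dims_px)
      conc[dv$idx] <- conc[dv$idx] + dv$val
    }
    dim(conc) <- dims_px
    conc_sum <- sum(conc)
    conc_sq_sum <- sum(conc^2)

    field <- spec$nonres_bg + spec$k_cars * conc^2
    field <- field + if (spec$membrane_amp > 0 && spec$membrane_bg > 0)
      spec$membrane_bg * .membrane_texture(dims_px, spec)
    else spec$membrane_bg
    psf_px <- c(spec$psf_sigma_um[1L] / px, spec$psf_sigma_um[1L] / px,
                spec$psf_sigma_um[2L] / zs)
    field <- .blur3d(field, psf_px)
    if (spec$noise_sd > 0)
      field <- field + rnorm(length(field), 0, spec$noise_sd)
    field[field < 0] <- 0
    if (spec$quantize) field <- pmin(round(field), 65535)

    af <- NULL
    if (any(npc)) {
      ind <- numeric(prod(dims_px))
      for (i in which(npc)) {
        dv <- .droplet_voxels(centers$x_um[i], centers$y_um[i],
                              centers$z_um[i], radii[i], 1, px, zs, dims_px)
        ind[dv$idx] <- ind[dv$idx] + dv$val
      }
      dim(ind) <- dims_px
      aff <- 5 + 100 * .blur3d(ind, psf_px)
      if (spec$noise_sd > 0)
        aff <- aff + rnorm(length(aff), 0, spec$noise_sd)
      aff[aff < 0] <- 0
      if (spec$quantize) aff <- pmin(round(aff), 65535)
      af <- voxel_volume(aff, px, zs, channel = "autofluorescence",
                         provenance = sprintf("synthetic (seed %d)", spec$seed))
    }
  })

  droplets <- data.frame(centers, r_um = radii, conc = rep(spec$droplet_conc, n),
                         npc = npc)
  truth <- structure(list(
    droplets = droplets,
    totals = list(count = n,
                  sphere_volume_um3 = sum(4 / 3 * pi * radii^3),
                  projected_area_um2 = sum(pi * radii^2)),
    counts_within_gates = sum(2 * radii >= 0.4 & 2 * radii <= 5),
    conc_voxel_sum = conc_sum,
    conc_sq_voxel_sum = conc_sq_sum,
    spec = spec), class = "GroundTruth")

  vol <- voxel_volume(field, px, zs, channel = "CARS",
                      provenance = sprintf("synthetic%s (seed %d)",
                                           if (is.na(spec$group)) "" else
                                             paste0(" ", spec$group),
                                           spec$seed))
  structure(list(volume = vol, truth = truth, autofluor = af),
            class = "SynthVolume")
}

#' @export
print.GroundTruth <- function(x, ...) {
  cat(sprintf(
    "GroundTruth: %d droplets, total sphere volume %.1f um^3, projected area %.1f um^2, %d within 0.4-5 um gates\n",
    x$totals$count, x$totals$sphere_volume_um3, x$totals$projected_area_um2,
    x$counts_within_gates))
  invisible(x)
}

#' @export
print.SynthVolume <- function(x, ...) {
  print(x$volume); print(x$truth)
  invisible(x)
}

#' Generate a seeded cohort of synthetic volumes for a severity group
#'
#' @param group severity preset, see [cohort_preset()].
#' @param n_volumes number of independent volumes.
#' @param seed base seed; volume `i` uses `seed + i - 1`.
#' @param ... overrides forwarded to [cohort_preset()].
#' @return a list of `SynthVolume` objects (length `n_volumes`).
#' @export
generate_cohort <- function(group, n_volumes, seed = 1L, ...) {
  if (!.is_count(n_volumes) || n_volumes < 1L)
    .stopf("`n_volumes` must be a positive count")
  lapply(seq_len(n_volumes), function(i) {
    spec <- cohort_preset(group, seed = as.integer(seed) + i - 1L, ...)
    generate_volume(spec)
  })
}
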