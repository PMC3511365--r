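#' Specification of a synthetic Raman spectrum
#'
#' A spectrum is a sum of Lorentzian bands over a smooth polynomial baseline
#' with additive Gaussian noise, sampled on a regular wavenumber axis.
#'
#' @param bands `data.frame` with columns `center` (cm^-1), `amplitude`
#'   (peak height, a.u., `>= 0`), `hwhm` (half-width at half-maximum,
#'   cm^-1, `> 0`).
#' @param baseline polynomial coefficients `c(b0, b1, ...)` of the baseline
#'   in the scaled variable `nu / 1000`.
#' @param noise_sd additive Gaussian noise sd (a.u.).
#' @param axis `c(min, max, step)` wavenumber axis in cm^-1, strictly
#'   increasing.
#' @param seed integer seed; identical specs generate identical spectra.
#' @return an object of class `BandSpec`.
#' @export
band_spec <- function(bands, baseline = 0, noise_sd = 0,
                      axis = c(600, 3100, 1), seed = 1L) {
  if (!is.data.frame(bands) ||
      !all(c("center", "amplitude", "hwhm") %in% names(bands)))
    .stopf("`bands` needs columns center, amplitude, hwhm")
  if (any(bands$hwhm <= 0)) .stopf("half-widths must be positive")
  if (any(bands$amplitude < 0)) .stopf("amplitudes must be nonnegative")
  if (length(axis) != 3L || axis[2L] <= axis[1L] || axis[3L] <= 0)
    .stopf("`axis` must be c(min, max, step) with max > min and step > 0")
  structure(list(bands = bands, baseline = baseline, noise_sd = noise_sd,
                 axis = axis, seed = as.integer(seed)),
            class = "BandSpec")
}

#' Lorentzian line profile
#'
#' `amplitude * hwhm^2 / ((nu - center)^2 + hwhm^2)`: peak height
#' `amplitude` at `center`, half that at `center +/- hwhm`.
#'
#' @param nu wavenumbers (cm^-1).
#' @param center,amplitude,hwhm band parameters.
#' @return intensities at `nu`.
#' @export
lorentzian <- function(nu, center, amplitude, hwhm) {
  amplitude * hwhm^2 / ((nu - center)^2 + hwhm^2)
}

#' Noise-free profile of a band specification
#'
#' @param spec a [band_spec()].
#' @param nu wavenumbers at which to evaluate (defaults to the spec's axis).
#' @return intensities: sum of Lorentzian bands plus polynomial baseline.
#' @export
band_profile <- function(spec, nu = NULL) {
  stopifnot(inherits(spec, "BandSpec"))
  if (is.null(nu))
    nu <- seq(spec$axis[1L], spec$axis[2L], by = spec$axis[3L])
  y <- numeric(length(nu))
  for (i in seq_len(nrow(spec$bands)))
    y <- y + lorentzian(nu, spec$bands$center[i], spec$bands$amplitude[i],
                        spec$bands$hwhm[i])
  for (j in seq_along(spec$baseline))
    y <- y + spec$baseline[j] * (nu / 1000)^(j - 1)
  y
}

#' Generate a seeded synthetic Raman spectrum
#'
#' @param spec a [band_spec()].
#' @return a [raman_spectrum()]; same seed, same spectrum.
#' @export
generate_spectrum <- function(spec) {
  stopifnot(inherits(spec, "BandSpec"))
  nu <- seq(spec$axis[1L], spec$axis[2L], by = spec$axis[3L])
  if (length(nu) < 2L) .stopf("axis produces fewer than two samples")
  y <- band_profile(spec, nu)
  if (spec$noise_sd > 0)
    y <- withr::with_seed(spec$seed, y + rnorm(length(y), 0, spec$noise_sd))
  raman_spectrum(nu, y, meta = sprintf("synthetic (seed %d)", spec$seed))
}

# peak height of the noiseless profile over a band window, measured the same
# way band_intensity() measures it (max minus local linear baseline) but on
# a dense closed-form evaluation
.closed_form_height <- function(spec, center, half_window, dense_step = 0.02) {
  nu <- seq(center - half_window, center + half_window, by = dense_step)
  y <- band_profile(spec, nu)
  base <- y[1L] + (y[length(y)] - y[1L]) *
    (nu - nu[1L]) / (nu[length(nu)] - nu[1L])
  max(max(y - base), 0)
}

#' Lipid-droplet Raman band presets by steatosis severity
#'
#' Builds a [band_spec()] carrying the canonical lipid-droplet band
#' inventory (1265, 1445, 1620, 1660, 1742, 2850, 2935 cm^-1). The
#' 1660 cm^-1 (C=C stretch) amplitude is calibrated numerically so that the
#' closed-form unsaturation ratio I1660/I1445 equals the group target:
#' 0.73 (`control`), 0.98 (`mild`), 1.1 (`severe`). For `npc = TRUE` the
#' 1620 cm^-1 marker amplitude is calibrated to the requested `npc_score`
#' (I1620/I1445), reproducing the distinctive spectral signature of
#' lipid-rich non-parenchymal cells.
#'
#' @param group severity preset.
#' @param npc simulate a lipid-rich non-parenchymal cell spectrum.
#' @param npc_score target I1620/I1445 when `npc = TRUE`.
#' @param unsat_ratio override the group's target I1660/I1445.
#' @param noise_sd,baseline,axis,seed forwarded to [band_spec()].
#' @return a calibrated `BandSpec`.
#' @export
lipid_band_preset <- function(group = c("control", "mild", "severe"),
                              npc = FALSE, npc_score = 0.6,
                              unsat_ratio = NULL,
                              noise_sd = 0.003, baseline = c(0.02, 0.01),
                              axis = c(600, 3100, 1), seed = 1L) {
  group <- match.arg(group)
  target <- unsat_ratio %||%
    switch(group, control = 0.73, mild = 0.98, severe = 1.1)
  bands <- data.frame(
    center    = c(1265, 1445, 1620, 1660, 1742, 2850, 2935),
    amplitude = c(0.18 + 0.12 * target, 0.45, 0, 0.3, 0.08, 1.0, 0.9),
    hwhm      = c(14, 12, 12, 12, 10, 10, 14))
  mk <- function(b) band_spec(b, baseline = baseline, noise_sd = noise_sd,
                              axis = axis, seed = seed)
  h1445 <- function(b) .closed_form_height(mk(b), 1445, 15)
  if (npc) {
    f <- function(a) {
      b <- bands; b$amplitude[b$center == 1620] <- a
      .closed_form_height(mk(b), 1620, 15) / h1445(b) - npc_score
    }
    bands$amplitude[bands$center == 1620] <-
      uniroot(f, c(0, 2), tol = 1e-7)$root
  }
  g <- function(a) {
    b <- bands; b$amplitude[b$center == 1660] <- a
    .closed_form_height(mk(b), 1660, 15) / h1445(b) - target
  }
  bands$amplitude[bands$center == 1660] <- uniroot(g, c(0, 2), tol = 1e-7)$root
  mk(bands)
}
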