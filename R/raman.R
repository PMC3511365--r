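#' Raman spectrum container
#'
#' @param wavenumber strictly increasing axis (cm^-1).
#' @param intensity intensities (a.u.), same length, finite.
#' @param meta free-text source label.
#' @return an object of class `RamanSpectrum`.
#' @export
raman_spectrum <- function(wavenumber, intensity, meta = "") {
  if (length(wavenumber) != length(intensity))
    .stopf("axis and intensity lengths differ")
  if (length(wavenumber) < 2L || any(diff(wavenumber) <= 0))
    .stopf("wavenumber axis must be strictly increasing")
  if (!all(is.finite(intensity))) .stopf("intensities must be finite")
  structure(list(wavenumber = as.numeric(wavenumber),
                 intensity = as.numeric(intensity), meta = meta),
            class = "RamanSpectrum")
}

#' @export
print.RamanSpectrum <- function(x, ...) {
  cat(sprintf("RamanSpectrum: %d points, %.0f-%.0f cm^-1  %s\n",
              length(x$wavenumber), min(x$wavenumber), max(x$wavenumber),
              x$meta))
  invisible(x)
}

#' Read / write spectra as two-column tables
#'
#' `read_spectrum()` accepts comma- or whitespace-delimited text with
#' columns wavenumber (cm^-1) and intensity; a non-numeric first line is
#' treated as a header. `write_spectrum()` writes CSV with a header.
#'
#' @param path file path.
#' @param meta source label for the returned spectrum.
#' @return a [raman_spectrum()].
#' @export
read_spectrum <- function(path, meta = basename(path)) {
  if (!file.exists(path)) .stopf("no such file: %s", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first)) "," else ""
  header <- is.na(suppressWarnings(as.numeric(strsplit(
    first, if (sep == ",") "," else "[[:space:]]+")[[1L]][1L])))
  tab <- read.table(path, sep = sep, header = header)
  if (ncol(tab) < 2L) .stopf("expected two columns in %s", path)
  raman_spectrum(tab[[1L]], tab[[2L]], meta = meta)
}

#' @rdname read_spectrum
#' @param spectrum a [raman_spectrum()].
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "RamanSpectrum"))
  df <- data.frame(wavenumber_cm1 = spectrum$wavenumber,
                   intensity = spectrum$intensity)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Canonical lipid-droplet band windows
#'
#' Named band centers and half-windows (cm^-1) used throughout the spectral
#' metrics. The C=C window (1645-1675 cm^-1) is wide enough to capture the
#' band whether it sits at 1654 or 1660 cm^-1.
#'
#' @return `data.frame` with columns `name`, `center`, `half_window`.
#' @export
band_set <- function() {
  data.frame(
    name = c("CH_deform", "CH2_bend", "npc_marker", "CC_stretch",
             "carbonyl", "CH2_sym", "CH3_sym"),
    center = c(1265, 1445, 1620, 1660, 1742, 2850, 2935),
    half_window = rep(15, 7L))
}

.resolve_band <- function(band) {
  bs <- band_set()
  if (is.character(band)) {
    i <- match(band, bs$name)
    if (is.na(i)) .stopf("unknown band '%s'", band)
    return(list(center = bs$center[i], half_window = bs$half_window[i]))
  }
  list(center = as.numeric(band), half_window = 15)
}

#' Baseline-corrected band peak height
#'
#' Peak height of a band: the maximum intensity within
#' `[center - half_window, center + half_window]` minus a local linear
#' baseline interpolated between the window edges (`baseline_mode =
#' "local_linear"`), clipped at zero. With `smooth = TRUE` (default) a
#' quadratic Savitzky-Golay filter (9 points) is applied first so the height
#' estimate is robust to point noise.
#'
#' @param spectrum a [raman_spectrum()].
#' @param band band name from [band_set()] or a numeric center (cm^-1).
#' @param half_window half-window override (cm^-1).
#' @param baseline_mode `"local_linear"` or `"raw"` (no baseline
#'   subtraction).
#' @param smooth apply Savitzky-Golay smoothing before peak picking.
#' @return nonnegative band intensity (a.u.).
#' @export
band_intensity <- function(spectrum, band, half_window = NULL,
                           baseline_mode = c("local_linear", "raw"),
                           smooth = TRUE) {
  stopifnot(inherits(spectrum, "RamanSpectrum"))
  baseline_mode <- match.arg(baseline_mode)
  b <- .resolve_band(band)
  hw <- half_window %||% b$half_window
  w <- spectrum$wavenumber
  lo <- b$center - hw; hi <- b$center + hw
  if (lo < min(w) || hi > max(w))
    .stopf("band window [%.0f, %.0f] lies outside the spectrum axis", lo, hi)
  y <- spectrum$intensity
  if (smooth && length(y) >= 9L)
    y <- signal::sgolayfilt(y, p = 2, n = 9L)
  idx <- which(w >= lo & w <= hi)
  if (length(idx) < 3L)
    .stopf("band window contains fewer than 3 samples")
  seg <- y[idx]; wseg <- w[idx]
  if (baseline_mode == "raw") return(max(max(seg), 0))
  nseg <- length(seg)
  base <- seg[1L] + (seg[nseg] - seg[1L]) *
    (wseg - wseg[1L]) / (wseg[nseg] - wseg[1L])
  max(max(seg - base), 0)
}

.band_ratio <- function(spectrum, num_band, den_band, ...) {
  den <- band_intensity(spectrum, den_band, ...)
  if (den == 0) {
    .warnf("denominator band %s has zero intensity; ratio undefined",
           as.character(den_band))
    return(NA_real_)
  }
  band_intensity(spectrum, num_band, ...) / den
}

#' Lipid-chain unsaturation ratio I1660/I1445
#'
#' Peak-height ratio of the C=C stretch to the CH2 bend band, a measure of
#' acyl-chain unsaturation. Returns `NA` (with a warning) if the denominator
#' band is absent.
#'
#' @param spectrum a [raman_spectrum()].
#' @param ... forwarded to [band_intensity()].
#' @return dimensionless ratio, or `NA` when undefined.
#' @export
unsaturation_ratio <- function(spectrum, ...) {
  .band_ratio(spectrum, "CC_stretch", "CH2_bend", ...)
}

#' Acyl packing-order ratio I2850/I2935
#'
#' Peak-height ratio of the CH2 to the CH3 symmetric stretch bands, a
#' measure of lipid packing order.
#'
#' @inheritParams unsaturation_ratio
#' @return dimensionless ratio, or `NA` when undefined.
#' @export
packing_ratio <- function(spectrum, ...) {
  .band_ratio(spectrum, "CH2_sym", "CH3_sym", ...)
}

#' Triglyceride signature test (1742 cm^-1 carbonyl)
#'
#' Esterified fatty acids carry a C=O carbonyl stretch at 1742 cm^-1. The
#' spectrum is called triglyceride-positive when
#' `I1742 / I1445 >= min_prominence` (boundary inclusive).
#'
#' @param spectrum a [raman_spectrum()].
#' @param min_prominence prominence threshold on the ratio.
#' @param ... forwarded to [band_intensity()].
#' @return logical.
#' @export
has_triglyceride_signature <- function(spectrum, min_prominence = 0.05, ...) {
  r <- .band_ratio(spectrum, "carbonyl", "CH2_bend", ...)
  !is.na(r) && r >= min_prominence
}

#' Classify a spectrum as hepatocyte or lipid-rich NPC
#'
#' Lipid-rich non-parenchymal cells (Kupffer cells) carry a distinctive
#' Raman band at 1620 cm^-1 that hepatocyte lipid droplets lack, and are
#' strongly autofluorescent around 510 nm. The NPC score is
#' `I1620 / I1445`; a cell is called `lipid_rich_NPC` when the score reaches
#' `npc_threshold`, or reaches half of it with corroborating
#' autofluorescence. A zero 1445 band makes the score undefined and the call
#' defaults to hepatocyte with a warning.
#'
#' @param spectrum a [raman_spectrum()].
#' @param autofluorescent was the cell autofluorescent in the 510/42 nm
#'   channel?
#' @param npc_threshold score threshold (boundary inclusive).
#' @param ... forwarded to [band_intensity()].
#' @return list with `class` (`"hepatocyte"` or `"lipid_rich_NPC"`),
#'   `npc_score`, and `defined`.
#' @export
classify_cell <- function(spectrum, autofluorescent = FALSE,
                          npc_threshold = 0.3, ...) {
  score <- .band_ratio(spectrum, "npc_marker", "CH2_bend", ...)
  if (is.na(score)) {
    .warnf("NPC score undefined (zero 1445 band); classifying as hepatocyte")
    return(list(class = "hepatocyte", npc_score = NA_real_, defined = FALSE))
  }
  npc <- score >= npc_threshold ||
    (score >= npc_threshold / 2 && isTRUE(autofluorescent))
  list(class = if (npc) "lipid_rich_NPC" else "hepatocyte",
       npc_score = score, defined = TRUE)
}

#' Full spectral metrics for one spectrum
#'
#' @param spectrum a [raman_spectrum()].
#' @param autofluorescent forwarded to [classify_cell()].
#' @param ... forwarded to [band_intensity()].
#' @return one-row `data.frame`: source, the seven band intensities,
#'   `unsat_ratio`, `packing_ratio`, `npc_score`, `class`.
#' @export
analyze_spectrum <- function(spectrum, autofluorescent = FALSE, ...) {
  bs <- band_set()
  ints <- vapply(bs$name, function(nm) band_intensity(spectrum, nm, ...),
                 numeric(1L))
  cl <- classify_cell(spectrum, autofluorescent = autofluorescent, ...)
  out <- data.frame(source = spectrum$meta, t(ints),
                    unsat_ratio = unsaturation_ratio(spectrum, ...),
                    packing_ratio = packing_ratio(spectrum, ...),
                    npc_score = cl$npc_score, class = cl$class,
                    stringsAsFactors = FALSE)
  names(out)[2:8] <- paste0("I", bs$center)
  out
}
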