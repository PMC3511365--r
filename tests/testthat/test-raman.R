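test_that("spectrum containers validate their axis", {
  expect_error(raman_spectrum(c(1, 2, 2), c(0, 0, 0)), "increasing")
  expect_error(raman_spectrum(1:3, 1:2), "lengths")
  expect_error(raman_spectrum(1:3, c(1, NA, 2)), "finite")
  expect_error(band_spec(data.frame(center = 1, amplitude = 1, hwhm = 0)),
               "half-widths")
  expect_error(band_spec(data.frame(center = 1, amplitude = 1, hwhm = 5),
                         axis = c(100, 50, 1)))
})

test_that("spectrum CSV and whitespace round-trips preserve the data", {
  s <- generate_spectrum(lipid_band_preset("control", seed = 3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectrum(s, path)
  back <- read_spectrum(path)
  expect_equal(back$wavenumber, s$wavenumber)
  expect_equal(back$intensity, s$intensity, tolerance = 1e-12)
  ws <- withr::local_tempfile(fileext = ".txt")
  writeLines(paste(s$wavenumber, s$intensity), ws)
  back2 <- read_spectrum(ws)
  expect_equal(back2$intensity, s$intensity, tolerance = 1e-12)
})

test_that("a lone Lorentzian's band intensity equals its amplitude", {
  sp <- band_spec(data.frame(center = 1445, amplitude = 0.7, hwhm = 10))
  s <- generate_spectrum(sp)
  # raw mode recovers the peak height exactly; the local-linear baseline
  # additionally subtracts the band's own wing level at the window edges
  expect_equal(band_intensity(s, "CH2_bend", baseline_mode = "raw"), 0.7,
               tolerance = 0.005)
  wing <- lorentzian(1445 + 15, 1445, 0.7, 10)
  expect_equal(band_intensity(s, "CH2_bend"), 0.7 - wing, tolerance = 0.01)
  # constant spectra have zero local-linear band height
  flat <- raman_spectrum(600:1800, rep(2, 1201))
  expect_equal(band_intensity(flat, "CH2_bend"), 0)
  expect_error(band_intensity(s, 3500), "outside")
})

test_that("overlapping bands match the dense closed-form window maximum", {
  sp <- band_spec(data.frame(center = c(1620, 1660), amplitude = c(0.5, 0.4),
                             hwhm = c(14, 12)), baseline = c(0.05, 0.02))
  s <- generate_spectrum(sp)
  for (ctr in c(1620, 1660))
    expect_equal(band_intensity(s, ctr), closed_form_height(sp, ctr),
                 tolerance = 0.01)
})

test_that("ratios are scale invariant and offset invariant", {
  s <- generate_spectrum(lipid_band_preset("mild", seed = 5))
  u <- unsaturation_ratio(s)
  p <- packing_ratio(s)
  scaled <- raman_spectrum(s$wavenumber, s$intensity * 7.3)
  offset <- raman_spectrum(s$wavenumber, s$intensity + 2.5)
  expect_equal(unsaturation_ratio(scaled), u, tolerance = 1e-12)
  expect_equal(packing_ratio(scaled), p, tolerance = 1e-12)
  expect_equal(unsaturation_ratio(offset), u, tolerance = 1e-12)
  expect_equal(packing_ratio(offset), p, tolerance = 1e-12)
})

test_that("equal-amplitude equal-width bands give unit ratios", {
  sp <- band_spec(data.frame(center = c(1445, 1660, 2850, 2935),
                             amplitude = rep(0.5, 4), hwhm = rep(10, 4)))
  s <- generate_spectrum(sp)
  expect_equal(unsaturation_ratio(s), 1, tolerance = 0.01)
  expect_equal(packing_ratio(s), 1, tolerance = 0.01)
})

test_that("group presets reproduce the reported unsaturation ratios", {
  for (tgt in c(control = 0.73, mild = 0.98, severe = 1.1)[c(1, 3)]) {
    g <- names(which(c(control = 0.73, mild = 0.98, severe = 1.1) == tgt))
    s <- generate_spectrum(lipid_band_preset(g, seed = 21))
    expect_equal(unsaturation_ratio(s), tgt, tolerance = 0.02 / tgt)
  }
})

test_that("zero denominator flags the ratio rather than crashing", {
  sp <- band_spec(data.frame(center = 1660, amplitude = 0.5, hwhm = 10))
  s <- generate_spectrum(sp)
  expect_warning(r <- unsaturation_ratio(s), "undefined")
  expect_true(is.na(r))
})

test_that("the carbonyl prominence rule is boundary inclusive", {
  mk <- function(a1742) generate_spectrum(band_spec(data.frame(
    center = c(1445, 1742), amplitude = c(0.6, a1742), hwhm = c(10, 10))))
  expect_false(has_triglyceride_signature(mk(0)))
  expect_true(has_triglyceride_signature(mk(0.3)))
  s <- mk(0.3)
  r <- band_intensity(s, "carbonyl") / band_intensity(s, "CH2_bend")
  expect_true(has_triglyceride_signature(s, min_prominence = r))
  expect_false(has_triglyceride_signature(s, min_prominence = r + 1e-9))
})

test_that("NPC classification follows the 1620 score and autofluorescence", {
  hep <- generate_spectrum(lipid_band_preset("control", seed = 6))
  npc <- generate_spectrum(lipid_band_preset("control", npc = TRUE,
                                             npc_score = 0.6, seed = 6))
  expect_equal(classify_cell(hep)$class, "hepatocyte")
  expect_equal(classify_cell(npc)$class, "lipid_rich_NPC")
  # absent 1620 band scores ~0
  expect_lt(classify_cell(hep)$npc_score, 0.05)
  # exact-threshold score classifies NPC (>= rule)
  sc <- classify_cell(npc)$npc_score
  expect_equal(classify_cell(npc, npc_threshold = sc)$class, "lipid_rich_NPC")
  # borderline score passes only with autofluorescence corroboration
  mid <- generate_spectrum(lipid_band_preset("control", npc = TRUE,
                                             npc_score = 0.2, seed = 7))
  expect_equal(classify_cell(mid)$class, "hepatocyte")
  expect_equal(classify_cell(mid, autofluorescent = TRUE)$class,
               "lipid_rich_NPC")
})

test_that("a spectrum without the CH2 bend band defaults to hepatocyte", {
  sp <- band_spec(data.frame(center = 1620, amplitude = 0.5, hwhm = 10),
                  axis = c(1300, 1800, 1))
  s <- generate_spectrum(sp)
  w <- capture_warnings(cl <- classify_cell(s))
  expect_true(any(grepl("hepatocyte", w)))
  expect_equal(cl$class, "hepatocyte")
  expect_false(cl$defined)
})

test_that("analyze_spectrum assembles the full metric row", {
  s <- generate_spectrum(lipid_band_preset("severe", seed = 8))
  row <- analyze_spectrum(s)
  expect_named(row, c("source", "I1265", "I1445", "I1620", "I1660", "I1742",
                      "I2850", "I2935", "unsat_ratio", "packing_ratio",
                      "npc_score", "class"))
  expect_equal(row$unsat_ratio, 1.1, tolerance = 0.02)
  expect_equal(row$class, "hepatocyte")
})
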