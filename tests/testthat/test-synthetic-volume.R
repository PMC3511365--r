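test_that("identical specs generate bit-identical volumes, different seeds differ", {
  a <- generate_volume(small_spec(seed = 7))
  b <- generate_volume(small_spec(seed = 7))
  c <- generate_volume(small_spec(seed = 8))
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$truth$droplets, b$truth$droplets)
  expect_false(identical(a$volume$data, c$volume$data))
})

test_that("droplet-free noiseless volume is the flat background everywhere", {
  sv <- generate_volume(small_spec(n_droplets = 0, noise_sd = 0,
                                   membrane_amp = 0))
  expect_true(all(sv$volume$data == sv$truth$spec$nonres_bg +
                    sv$truth$spec$membrane_bg))
})

test_that("ground-truth totals are exact functions of the droplet list", {
  sv <- generate_volume(small_spec(n_droplets = 12, seed = 3))
  d <- sv$truth$droplets
  expect_equal(sv$truth$totals$count, nrow(d))
  expect_equal(sv$truth$totals$sphere_volume_um3, sum(4 / 3 * pi * d$r_um^3))
  expect_equal(sv$truth$totals$projected_area_um2, sum(pi * d$r_um^2))
  expect_lte(sv$truth$counts_within_gates, sv$truth$totals$count)
  # single unit-radius droplet: projected disc area is pi
  one <- generate_volume(small_spec(n_droplets = 1, radius_median_um = 1,
                                    radius_sigma = 1e-6))
  expect_equal(one$truth$totals$projected_area_um2, pi, tolerance = 1e-3)
})

test_that("voxelized concentration integrates to the sphere volume at fine sampling", {
  # 0.1 um sampling in all three axes; conc_voxel_sum / conc * voxel volume
  # is a numerical integral of the droplet indicator
  sv <- generate_volume(volume_spec(
    dims_um = c(6, 6, 4), lateral_px_um = 0.1, z_step_um = 0.1,
    n_droplets = 1, radius_median_um = 0.8, radius_sigma = 1e-6,
    r_min_um = 0.5, r_max_um = 1.2, noise_sd = 0, membrane_amp = 0, seed = 2))
  vox_vol <- 0.1 * 0.1 * 0.1
  integral <- sv$truth$conc_voxel_sum / sv$truth$spec$droplet_conc * vox_vol
  expect_equal(integral, sv$truth$totals$sphere_volume_um3, tolerance = 0.02)
})

test_that("mean intensity grows strictly with droplet concentration", {
  lv <- vapply(c(10, 20, 40), function(conc) {
    mean(generate_volume(small_spec(droplet_conc = conc, noise_sd = 0,
                                    seed = 4))$volume$data)
  }, numeric(1L))
  expect_true(all(diff(lv) > 0))
})

test_that("the PSF conserves total intensity", {
  base <- small_spec(noise_sd = 0, quantize = FALSE, seed = 6)
  no_psf <- base
  no_psf$psf_sigma_um <- c(0, 0)
  s1 <- sum(generate_volume(base)$volume$data)
  s0 <- sum(generate_volume(no_psf)$volume$data)
  expect_equal(s1 / s0, 1, tolerance = 0.005)
})

test_that("infeasible packing fails with an explicit density message", {
  expect_error(
    generate_volume(volume_spec(dims_um = c(12, 12, 8),
                                lateral_px_um = 12 / 64, n_droplets = 200,
                                radius_median_um = 1.2, seed = 1)),
    "packing density")
})

test_that("cohort presets carry the group droplet burden", {
  ctrl <- cohort_preset("control")
  sev <- cohort_preset("severe")
  expect_equal(ctrl$n_droplets, 50L)
  expect_equal(cohort_preset("mild")$n_droplets, 300L)
  expect_equal(sev$n_droplets, 800L)
  expect_equal(sev$mean_area_um2, 10.2)
  # calibrated radius distribution reproduces the target mean projected area
  for (g in c("control", "mild", "severe")) {
    sp <- cohort_preset(g)
    r <- pmin(pmax(stats::rlnorm(2e5, log(sp$radius_median_um),
                                 sp$radius_sigma), sp$r_min_um), sp$r_max_um)
    expect_equal(mean(pi * r^2), sp$mean_area_um2, tolerance = 0.02)
  }
  expect_error(cohort_preset("moderate"))
})

test_that("cohort volumes are seeded independently and reproducibly", {
  co1 <- generate_cohort("control", 3, seed = 10, dims_um = c(40, 40, 10),
                         lateral_px_um = 40 / 128, n_droplets = 8)
  co2 <- generate_cohort("control", 3, seed = 10, dims_um = c(40, 40, 10),
                         lateral_px_um = 40 / 128, n_droplets = 8)
  expect_identical(co1[[1]]$volume$data, co2[[1]]$volume$data)
  expect_false(identical(co1[[1]]$volume$data, co1[[2]]$volume$data))
  expect_false(identical(co1[[2]]$volume$data, co1[[3]]$volume$data))
})

test_that("autofluorescence channel marks NPC droplets", {
  sv <- generate_volume(small_spec(autofluor_fraction = 1, seed = 9))
  expect_true(all(sv$truth$droplets$npc))
  expect_s3_class(sv$autofluor, "VoxelVolume")
  expect_identical(sv$autofluor$channel, "autofluorescence")
  expect_gt(max(sv$autofluor$data), 3 * median(sv$autofluor$data))
  none <- generate_volume(small_spec(autofluor_fraction = 0, seed = 9))
  expect_null(none$autofluor)
})
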