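test_that("the 5% area-fraction rule decides steatosis presence inclusively", {
  q <- manual_quant()
  # field 1000 um^2: 49 um^2 of droplets -> 4.9%, below threshold
  below <- manual_seg(kept_areas = rep(1.225, 40))
  stats_b <- droplet_statistics(below, c(25, 40, 10))
  expect_equal(grade_steatosis(q, stats_b, below)$grade, "none")
  # exactly 5.0% with all droplets small -> microvesicular (>= rule)
  at <- manual_seg(kept_areas = rep(1.25, 40))
  stats_a <- droplet_statistics(at, c(25, 40, 10))
  rep_a <- grade_steatosis(q, stats_a, at)
  expect_equal(rep_a$lipid_area_fraction, 0.05)
  expect_equal(rep_a$grade, "microvesicular")
})

test_that("macro and mixed grades follow the large-droplet area share", {
  q <- manual_quant()
  big <- pi * (6 / 2)^2   # a 6-um component (an upper-gate reject)
  # 28.3 um^2 large + 60 um^2 small: share 32% -> macrovesicular
  seg_macro <- manual_seg(kept_areas = rep(1.5, 40),
                          rejected_areas = big, rejected_reason = "large")
  st <- droplet_statistics(seg_macro, c(25, 40, 10))
  expect_equal(grade_steatosis(q, st, seg_macro)$grade, "macrovesicular")
  # share between 5% and 25% -> mixed
  seg_mixed <- manual_seg(kept_areas = rep(1.5, 100),
                          rejected_areas = c(21, 21),  # equiv diam 5.2 um
                          rejected_reason = c("large", "large"),
                          field_area_um2 = 2000)
  st2 <- droplet_statistics(seg_mixed, c(50, 40, 10))
  g <- grade_steatosis(q, st2, seg_mixed)
  expect_gt(g$macro_area_share, 0.05)
  expect_lt(g$macro_area_share, 0.25)
  expect_equal(g$grade, "mixed")
})

test_that("zero droplets grade none but keep the fold change", {
  q <- manual_quant(level = 2, normalized = 1.7)
  seg <- manual_seg(numeric())
  st <- droplet_statistics(seg, c(25, 40, 10))
  rep0 <- grade_steatosis(q, st, seg)
  expect_equal(rep0$grade, "none")
  expect_equal(rep0$fold_change_vs_reference, 1.7)
})

test_that("grading is monotone: adding droplet area never un-calls steatosis", {
  q <- manual_quant()
  areas <- seq(10, 120, by = 10)
  grades <- vapply(areas, function(a) {
    seg <- manual_seg(kept_areas = rep(a / 20, 20))
    grade_steatosis(q, droplet_statistics(seg, c(25, 40, 10)), seg)$grade
  }, character(1L))
  present <- grades != "none"
  expect_true(all(diff(present) >= 0))
})

test_that("mismatched segmentation and volume dimensions are caught", {
  q <- manual_quant()
  seg <- manual_seg(kept_areas = rep(1.5, 10))       # field 1000 um^2
  st <- droplet_statistics(seg, c(100, 100, 10))     # claims 10000 um^2
  expect_error(grade_steatosis(q, st, seg), "mismatch")
})

test_that("reports serialize to JSON and back identically", {
  q <- manual_quant(level = 2, normalized = 1.7, id = "v1", group = "tg")
  seg <- manual_seg(kept_areas = rep(2, 30))
  rep1 <- grade_steatosis(q, droplet_statistics(seg, c(25, 40, 10)), seg)
  rep2 <- report_from_json(report_to_json(rep1))
  expect_equal(rep2, rep1)
  expect_identical(report_to_json(rep2), report_to_json(rep1))
})

test_that("group comparison orders groups and references fold changes", {
  mk <- function(id, group, norm) {
    q <- manual_quant(level = norm, normalized = norm, id = id, group = group)
    seg <- manual_seg(kept_areas = rep(2, 30))
    grade_steatosis(q, droplet_statistics(seg, c(25, 40, 10)), seg)
  }
  reports <- list(mk("a", "wt", 0.9), mk("b", "wt", 1.1),
                  mk("c", "tg", 3.0), mk("d", "tg", 3.2))
  tab <- compare_groups(reports, "wt")
  expect_equal(tab$group, c("tg", "wt"))
  expect_equal(tab$fold_change[tab$group == "wt"], 1)
  expect_equal(tab$fold_change[tab$group == "tg"], 3.1)
  expect_error(compare_groups(reports, "ko"), "unknown")
  expect_error(compare_groups(list(), "wt"), "no reports")
})

test_that("a 2:1 concentration contrast yields a ~2x fold change end to end", {
  mkvol <- function(conc, seed)
    generate_volume(small_spec(n_droplets = 10, droplet_conc = conc,
                               noise_sd = 0, membrane_amp = 0,
                               seed = seed))$volume
  vols <- c(lapply(1:3, function(s) mkvol(15, s)),
            lapply(1:3, function(s) mkvol(30, s)))
  res <- analyze_cohort(vols, rep(c("wt", "hi"), each = 3), "wt")
  fc <- res$summary$fold_change[res$summary$group == "hi"]
  expect_equal(fc, 2, tolerance = 0.05)
  expect_equal(res$summary$fold_change[res$summary$group == "wt"], 1)
})
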