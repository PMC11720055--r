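test_that("voxel-count volumetry is exact arithmetic", {
  m <- array(FALSE, c(10, 10, 10))
  m[1:4, 1:5, 1:5] <- TRUE                      # 100 voxels
  expect_equal(nodule_volume(m, c(0.7, 0.7, 1.0)), 49)
  expect_message(v0 <- nodule_volume(array(FALSE, c(4, 4, 4)), c(1, 1, 1)),
                 "empty")
  expect_equal(v0, 0)
  expect_error(nodule_volume(array(1, c(4, 4, 4)), c(1, 1, 1)), "binary")
})

test_that("volumetry is additive over disjoint masks", {
  set.seed(4)
  m1 <- array(runif(6^3) < 0.3, c(6, 6, 6))
  m2 <- array(runif(6^3) < 0.3, c(6, 6, 6)) & !m1
  sp <- c(0.5, 0.6, 1.2)
  expect_equal(nodule_volume(m1 | m2, sp),
               nodule_volume(m1, sp) + nodule_volume(m2, sp))
})

test_that("nodule typing applies the -450 HU rule with the boundary on the GGN side", {
  m <- array(FALSE, c(6, 6, 6)); m[2:4, 2:4, 2:4] <- TRUE
  mk <- function(hu) ct_volume(array(hu, c(6, 6, 6)), c(1, 1, 1))
  expect_equal(classify_nodule_type(mk(-300), m), "solid")
  expect_equal(classify_nodule_type(mk(-450), m), "GGN")     # exactly at threshold
  expect_equal(classify_nodule_type(mk(-449.999), m), "solid")
  expect_equal(classify_nodule_type(mk(-600), m), "GGN")
  mixed <- mk(-300)
  mixed$voxels[2, 2:3, 2:4] <- -600
  expect_equal(classify_nodule_type(mixed, m), "subsolid")
  expect_error(classify_nodule_type(mk(0), array(FALSE, c(6, 6, 6))), "empty")
})

test_that("typing depends only on the masked HU multiset", {
  set.seed(6)
  m <- array(FALSE, c(5, 5, 5)); m[2:4, 2:4, 2:4] <- TRUE
  hu <- c(rep(-300, 13), rep(-600, 14))
  v1 <- ct_volume(array(-850, c(5, 5, 5)), c(1, 1, 1))
  v2 <- v1
  v1$voxels[m] <- hu
  v2$voxels[m] <- sample(hu)                    # permuted within the mask
  expect_equal(classify_nodule_type(v1, m), classify_nodule_type(v2, m))
})

test_that("solid component and its low-attenuation complement partition the total", {
  fx <- centered_sphere_phantom(3, 0.5, 24, core_hu = -100)
  vol <- fx$phantom$volume; mask <- fx$phantom$masks[[1]]
  sp <- vol$spacing_mm
  total <- nodule_volume(mask, sp)
  solid <- solid_component_volume(vol, mask, sp)
  ggn_side <- sum(mask$mask & vol$voxels <= -450) * prod(sp)
  expect_equal(solid + ggn_side, total)
  expect_equal(solid, total)                    # solid nodule: component = total
  ggn <- centered_sphere_phantom(3, 0.5, 24, core_hu = -700)
  expect_equal(solid_component_volume(ggn$phantom$volume, ggn$phantom$masks[[1]], sp), 0)
})

test_that("part-solid core volume measures within 8% of its analytic value", {
  gs <- rep(28, 3); sp <- rep(0.5, 3)
  ctr <- (gs - 1) * sp / 2
  ns <- nodule_spec(ctr, c(4, 4, 4), core_hu = -100, shell_hu = -700,
                    core_radii_mm = c(2, 2, 2))
  ph <- make_phantom(phantom_spec(gs, sp, nodule_specs = list(ns), seed = 3))
  comp <- solid_component_volume(ph$volume, ph$masks[[1]], sp)
  expect_equal(classify_nodule_type(ph$volume, ph$masks[[1]]), "subsolid")
  expect_lt(abs(comp - 4 / 3 * pi * 8) / (4 / 3 * pi * 8), 0.08)
})

test_that("repeatability statistics reproduce the published worked examples", {
  e1 <- repeatability_stats(c(133, 121, 146, 142, 144))
  expect_equal(round(e1$mean_mm3, 1), 137.2)
  expect_equal(round(e1$cv_percent, 2), 6.73)
  e2 <- repeatability_stats(c(137, 140, 133, 125, 148))
  expect_equal(round(e2$mean_mm3, 1), 136.6)
  expect_equal(round(e2$sd_mm3, 2), 7.61)
  expect_equal(round(e2$cv_percent, 2), 5.57)
  # the population-SD convention is the discriminating choice: the sample
  # convention would print 8.50, not 7.61
  expect_equal(round(sd(c(137, 140, 133, 125, 148)), 2), 8.50)
})

test_that("repeatability statistics validate their input", {
  cst <- repeatability_stats(c(100, 100, 100))
  expect_equal(cst$sd_mm3, 0)
  expect_equal(cst$cv_percent, 0)
  expect_error(repeatability_stats(137), "at least 2")
  expect_error(repeatability_stats(c(100, -5)), "positive")
})

test_that("nodule records enforce type/component consistency", {
  expect_silent(nodule_record("n1", "solid", 100, 100))
  expect_silent(nodule_record("n2", "GGN", 50, 0))
  expect_silent(nodule_record("n3", "subsolid", 150, 60))
  expect_error(nodule_record("n4", "solid", 100, 60), "equal its total")
  expect_error(nodule_record("n5", "GGN", 50, 10), "must be 0")
  expect_error(nodule_record("n6", "subsolid", 100, 130), "\\[0, total")
})

test_that("measure_nodules assembles consistent per-nodule records", {
  study <- phantom_study_set(1, seed = 4)[[1]]
  rec <- measure_nodules(study$volume, study$masks, source = "thin")
  expect_equal(nrow(rec), 3)
  expect_setequal(rec$type, c("solid", "GGN", "subsolid"))
  expect_true(all(rec$solid_mm3 >= 0 & rec$solid_mm3 <= rec$total_mm3))
  expect_equal(rec$type, vapply(study$specs, `[[`, character(1), "intended_type"))
})
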