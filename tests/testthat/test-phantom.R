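# Synthetic pelvic phantom and its ground-truth deformations.

test_that("phantom generation is seeded-deterministic and anatomically valid", {
  spec <- desk_spec()
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$image$data, b$image$data)
  expect_identical(a$labels$data, b$labels$data)
  # all three organs present, non-overlapping by construction
  for (org in c("prostate", "bladder", "rectum"))
    expect_gt(sum(mask_of(a$labels, org)), 100)
  # different seed changes the noise but not the labels
  c2 <- generate_phantom(phantom_spec(scale = 72 / 140, seed = 7L))
  expect_identical(c2$labels$data, a$labels$data)
  expect_false(identical(c2$image$data, a$image$data))
})

test_that("a 23 mm spherical prostate has the study's median volume of ~51 ml", {
  spec <- phantom_spec(prostate = list(center = c(70, 70, 62),
                                       semiaxes = c(23, 23, 23)),
                       bladder = list(center = c(70, 38, 106),
                                      semiaxes = c(26, 24, 24)))
  ph <- generate_phantom(spec)
  vol <- organ_volume(ph$labels, "prostate")
  expect_lt(abs(vol - 4 / 3 * pi * 23^3 / 1000) / (4 / 3 * pi * 23^3 / 1000),
            0.02)
  expect_equal(vol, 51.0, tolerance = 0.02)
})

test_that("zero noise gives piecewise-constant intensities per organ", {
  spec <- phantom_spec(scale = 0.4,
                       intensity = list(means = c(background = 30,
                                                  prostate = 90, bladder = 160,
                                                  rectum = 50), noise_sd = 0))
  ph <- generate_phantom(spec)
  for (org in c("prostate", "bladder", "rectum")) {
    vals <- ph$image$data[mask_of(ph$labels, org)]
    expect_equal(stats::sd(vals), 0)
  }
})

test_that("overlapping organ specifications raise a geometry error naming the pair", {
  spec <- phantom_spec(scale = 0.4,
                       bladder = list(center = c(70, 60, 70),
                                      semiaxes = c(30, 26, 26)))
  expect_error(generate_phantom(spec), "prostate and bladder")
})

test_that("synthetic deformation is zero at zero scale and exactly linear", {
  ph <- desk_phantom()
  z <- generate_synthetic_deformation(ph, 0, seed = 3, fem = desk_fem())
  expect_equal(max(abs(z$field$data)), 0)
  s1 <- generate_synthetic_deformation(ph, 1, seed = 3, fem = desk_fem())
  s2 <- generate_synthetic_deformation(ph, 2, seed = 3, fem = desk_fem())
  expect_equal(s2$field$data, 2 * s1$field$data, tolerance = 1e-8)
})

test_that("force-scale calibration reaches the target starting Dice", {
  ph <- desk_phantom()
  dd <- desk_deformed(1)
  pro <- mask_of(ph$labels, "prostate")
  start <- dice_coefficient(pro, mask_of(dd$labels, "prostate"))
  expect_equal(start, 0.65, tolerance = 0.011)
  # a target within tolerance of no deformation returns scale ~0
  s0 <- calibrate_force_scale(ph, 1 - 0.005, tolerance = 0.01, seed = 1,
                              fem = desk_fem())
  expect_equal(as.numeric(s0), 0)
})

test_that("Dice decreases monotonically with the deformation scale", {
  ph <- desk_phantom()
  dd <- desk_deformed(1)
  pro <- mask_of(ph$labels, "prostate")
  unit <- attr(calibrate_force_scale(ph, 0.65, seed = 1, fem = desk_fem()),
               "deformation")
  dice_at <- function(s) {
    f <- dispfield(unit$field$data * s, ph$labels$spacing, ph$labels$origin)
    dice_coefficient(pro, mask_of(warp_image(ph$labels, f), "prostate"))
  }
  d <- vapply(c(0, 0.25, 0.5, 1, 2) * dd$scale, dice_at, numeric(1))
  expect_true(all(diff(d) <= 0.005))
})

test_that("focal lesion embedding hits the volume target with a local peak", {
  ph <- desk_phantom()
  labels <- ph$labels
  pidx <- which(mask_of(labels, "prostate"), arr.ind = TRUE)
  site <- labels$origin + (colMeans(pidx) - 1) * labels$spacing + c(3, 4, 0)
  les <- embed_focal_lesion(ph, site, shrink_fraction = 0.05,
                            intensity_delta = 25)
  v0 <- organ_volume(labels, "prostate")
  v1 <- organ_volume(les$labels, "prostate")
  expect_equal(100 * (v1 - v0) / v0, -5, tolerance = 0.1)
  m <- magnitude_map(les$field)
  peak <- m$origin + (as.numeric(arrayInd(which.max(m$data), dim(m$data))) - 1) *
    m$spacing
  expect_lt(sqrt(sum((peak - site)^2)), 10)
  # degenerate case: nothing requested, nothing changes
  les0 <- embed_focal_lesion(ph, site, 0, 0)
  expect_equal(max(abs(les0$field$data)), 0)
  expect_identical(les0$image$data, ph$image$data)
  # a site outside the prostate is a geometry error
  expect_error(embed_focal_lesion(ph, c(1, 1, 1), 0.05, 10), "outside")
})
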