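# Mutual information and the 9-parameter linear alignment.

test_that("mutual information equals marginal entropy for identical images", {
  ph <- small_phantom()
  a <- ph$image
  mi <- mutual_information(a, a, bins = 32)
  # independent marginal-entropy oracle with the same binning
  v <- as.numeric(a$data)
  r <- range(v)
  ix <- pmin(floor((v - r[1]) / (r[2] - r[1]) * 32) + 1L, 32L)
  p <- tabulate(ix, 32) / length(v)
  H <- -sum(p[p > 0] * log(p[p > 0]))
  expect_equal(mi, H, tolerance = 1e-9)
})

test_that("mutual information is symmetric, non-negative and histogram-invariant", {
  ph <- small_phantom()
  a <- ph$image
  b <- vol3d(a$data[, , dim(a$data)[3]:1], a$spacing, a$origin)
  expect_equal(mutual_information(a, b), mutual_information(b, a),
               tolerance = 1e-12)
  expect_gte(mutual_information(a, b), -1e-12)
  # independent noise: MI near zero
  set.seed(61)
  n1 <- vol3d(array(rnorm(64^3), c(64, 64, 64)))
  n2 <- vol3d(array(rnorm(64^3), c(64, 64, 64)))
  expect_lt(mutual_information(n1, n2), 0.05)
  # a bin-preserving monotone remap leaves MI(a, a) unchanged
  remap <- vol3d(2 * a$data + 7, a$spacing, a$origin)
  expect_equal(mutual_information(a, remap), mutual_information(a, a),
               tolerance = 1e-9)
  # constant image degenerates with a warning
  const <- vol3d(array(1, dim(a$data)), a$spacing, a$origin)
  expect_warning(mi0 <- mutual_information(a, const), "constant")
  expect_equal(mi0, 0)
})

test_that("linear transforms compose to matrices and apply exactly", {
  t1 <- linear_transform(translation = c(1, 2, 3),
                         rotation = c(0.1, -0.2, 0.3),
                         scale = c(1.1, 0.9, 1), center = c(5, 5, 5))
  M <- as_matrix(t1)
  expect_equal(dim(M), c(4L, 4L))
  expect_equal(as.numeric(M[4, ]), c(0, 0, 0, 1))
  # identity transform preserves the image bitwise under nearest resampling
  ph <- small_phantom()
  idt <- linear_transform()
  out <- apply_linear(ph$labels, idt)
  expect_identical(out$data, ph$labels$data)
  # translation by exactly one voxel shifts indices
  sh <- linear_transform(translation = c(ph$image$spacing[1], 0, 0))
  w <- apply_linear(ph$image, sh, interp = "nearest")
  d <- dim(ph$image$data)
  expect_equal(w$data[2:d[1], , ], ph$image$data[1:(d[1] - 1), , ],
               ignore_attr = TRUE)
})

test_that("registration recovers identity, translation and scale", {
  ph <- small_phantom()
  img <- ph$image
  center <- img$origin + (dim(img$data) - 1) * img$spacing / 2
  # moving == fixed: transform within tight tolerances of identity
  t_id <- register_linear(img, img)
  expect_lt(max(abs(t_id$translation)), 0.5)
  expect_lt(max(abs(t_id$rotation)), 0.01)
  expect_lt(max(abs(t_id$scale - 1)), 0.005)
  # known translation (5, -3, 2) mm with 5% noise: recovered within 1 mm
  tt <- linear_transform(translation = c(5, -3, 2), center = center)
  moving <- apply_linear(img, tt, grid = img)
  set.seed(62)
  moving$data <- moving$data +
    rnorm(length(moving$data), sd = 0.05 * diff(range(img$data)))
  tr <- register_linear(moving, img)
  expect_lt(max(abs(tr$translation - c(-5, 3, -2))), 1)
  # isotropic scale 1.05: recovered within 1 percent
  ts <- linear_transform(scale = rep(1.05, 3), center = center)
  mov2 <- apply_linear(img, ts, grid = img)
  tr2 <- register_linear(mov2, img)
  expect_lt(max(abs(tr2$scale - 1 / 1.05)), 0.01)
  # accepted objective values never decrease
  tel <- attr(tr, "telemetry")
  for (lvl in tel) expect_true(all(diff(lvl) >= -1e-12))
})

test_that("matrix round trip is lossless and apply-then-invert preserves overlap", {
  center <- c(5, -2, 8)
  t1 <- linear_transform(translation = c(3, -2, 1),
                         rotation = c(0.05, 0.02, -0.03),
                         scale = c(1.02, 0.98, 1.01), center = center)
  t2 <- linear_transform_from_matrix(as_matrix(t1), center = center)
  expect_equal(as_matrix(t2), as_matrix(t1), tolerance = 1e-12)
  expect_equal(t2$rotation, t1$rotation, tolerance = 1e-12)
  expect_equal(t2$scale, t1$scale, tolerance = 1e-12)
  # warp labels forward and back: prostate Dice stays high
  ph <- small_phantom()
  fwd <- apply_linear(ph$labels, t1, grid = ph$labels)
  back <- apply_linear(fwd, invert_linear(t1), grid = ph$labels)
  expect_gt(dice_coefficient(mask_of(ph$labels, "prostate"),
                             mask_of(back, "prostate")), 0.98)
})
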