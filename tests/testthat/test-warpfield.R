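# Dense fields: nodal interpolation, warping, composition, inversion.

test_that("all interpolation schemes are partitions of unity", {
  lm <- cube_labelmap(6, pad = 1)
  mesh <- build_mesh(lm, 1, 1, margin = 0)
  n <- nrow(mesh$nodes)
  u0 <- c(0.3, -1.2, 2.5)
  U <- matrix(u0, n, 3, byrow = TRUE)
  grid <- vol3d(array(0, c(6, 6, 6)), c(1, 1, 1), c(1.2, 1.2, 1.2))
  for (scheme in c("trilinear", "as_printed", "inverse_distance")) {
    f <- interpolate_displacements(mesh, U, grid, scheme = scheme)
    for (k in 1:3)
      expect_equal(max(abs(f$data[, , , k] - u0[k])), 0, tolerance = 1e-9)
  }
})

test_that("trilinear interpolation reproduces affine nodal fields exactly", {
  lm <- cube_labelmap(6, pad = 1)
  mesh <- build_mesh(lm, 1, 1, margin = 0)
  set.seed(51)
  A <- matrix(rnorm(9, sd = 0.1), 3, 3)
  b <- rnorm(3)
  U <- mesh$nodes %*% t(A) + matrix(b, nrow(mesh$nodes), 3, byrow = TRUE)
  grid <- vol3d(array(0, c(5, 5, 5)), c(1, 1, 1), c(1.7, 1.7, 1.7))
  f <- interpolate_displacements(mesh, U, grid)
  p <- femablate:::voxel_centers(grid)
  truth <- p %*% t(A) + matrix(b, nrow(p), 3, byrow = TRUE)
  est <- matrix(f$data, ncol = 3)
  expect_lt(max(abs(est - truth)), 1e-9)
})

test_that("a voxel coincident with a node takes that node's displacement", {
  lm <- cube_labelmap(4, pad = 1)
  mesh <- build_mesh(lm, 1, 1, margin = 0)
  set.seed(52)
  U <- matrix(rnorm(3 * nrow(mesh$nodes)), ncol = 3)
  node <- 40L
  grid <- vol3d(array(0, c(1, 1, 1)), c(1, 1, 1), mesh$nodes[node, ])
  f <- interpolate_displacements(mesh, U, grid)
  expect_equal(as.numeric(f$data[1, 1, 1, ]), U[node, ], tolerance = 1e-9)
  # inverse-distance also honours coincidence; the literal distance
  # weighting gives the coincident node weight zero instead
  fi <- interpolate_displacements(mesh, U, grid, scheme = "inverse_distance")
  expect_equal(as.numeric(fi$data[1, 1, 1, ]), U[node, ], tolerance = 1e-3)
  fp <- interpolate_displacements(mesh, U, grid, scheme = "as_printed")
  expect_gt(max(abs(as.numeric(fp$data[1, 1, 1, ]) - U[node, ])), 1e-3)
})

test_that("warping with zero or integer-translation fields is exact", {
  ph <- small_phantom()
  img <- ph$image
  zero <- dispfield(array(0, c(dim(img$data), 3)), img$spacing, img$origin)
  expect_identical(warp_image(img, zero, interp = "nearest")$data, img$data)
  expect_equal(warp_image(img, zero, interp = "linear")$data, img$data,
               tolerance = 1e-6)
  # +2 voxels in x: output equals the index-shifted input
  tf <- zero; tf$data[, , , 1] <- 2
  w <- warp_image(img, tf, interp = "nearest")
  d <- dim(img$data)
  expect_equal(w$data[1:(d[1] - 2), , ], img$data[3:d[1], , ],
               ignore_attr = TRUE)
  # labels warp with nearest and never invent labels
  wl <- warp_image(ph$labels, tf)
  expect_true(all(wl$data %in% unique(as.integer(ph$labels$data))))
  # geometry mismatch errors
  bad <- dispfield(array(0, c(4, 4, 4, 3)))
  expect_error(warp_image(img, bad), "differ")
})

test_that("composition behaves as sequential warping and sums translations", {
  ph <- small_phantom()
  img <- ph$image
  d <- dim(img$data)
  mk <- function(v) {
    a <- array(0, c(d, 3))
    for (k in 1:3) a[, , , k] <- v[k]
    dispfield(a, img$spacing, img$origin)
  }
  f <- mk(c(1.5, -2, 0.5))
  zero <- mk(c(0, 0, 0))
  expect_equal(compose_fields(list(f, zero))$data, f$data, tolerance = 1e-6)
  g <- mk(c(-0.5, 1, 2))
  comp_t <- compose_fields(list(f, g))$data
  inner0 <- 5:(min(d) - 5)
  expect_equal(comp_t[inner0, inner0, inner0, ],
               mk(c(1, -1, 2.5))$data[inner0, inner0, inner0, ],
               tolerance = 1e-6, ignore_attr = TRUE)
  # composed field equals applying the two warps one after the other
  s <- mk(c(0, 0, 0))
  X <- array(rep(seq_len(d[1]), times = d[2] * d[3]), d)
  s$data[, , , 1] <- 1.5 * sin(2 * pi * X / 25)
  s$data[, , , 3] <- 1.0 * cos(2 * pi * X / 30)
  seq_warp <- warp_image(warp_image(img, f), s)
  one_warp <- warp_image(img, compose_fields(list(f, s)))
  inner <- 5:(min(d) - 5)
  expect_equal(seq_warp$data[inner, inner, inner],
               one_warp$data[inner, inner, inner], tolerance = 0.2,
               ignore_attr = TRUE)
  expect_error(compose_fields(list()), "empty")
})

test_that("numeric inversion composes with the field to near identity", {
  ph <- desk_phantom()
  # small-strain instance: gradients well below 1, the contraction regime
  # of the fixed-point iteration
  syn <- generate_synthetic_deformation(ph, 0.1, seed = 5, fem = desk_fem())
  f <- syn$field
  inv <- invert_field(f)
  comp <- compose_fields(list(f, inv))
  m <- magnitude_map(comp)
  # away from the boundary the residual is small for this smooth field
  d <- dim(m$data)
  inner <- m$data[8:(d[1] - 8), 8:(d[2] - 8), 8:(d[3] - 8)]
  expect_lt(max(inner), 0.1)
})

test_that("magnitude maps report the Euclidean norm in mm", {
  a <- array(0, c(3, 3, 3, 3))
  a[, , , 1] <- 3; a[, , , 2] <- 4
  f <- dispfield(a)
  expect_equal(max(abs(magnitude_map(f)$data - 5)), 0)
  z <- dispfield(array(0, c(2, 2, 2, 3)))
  expect_equal(max(magnitude_map(z)$data), 0)
})
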