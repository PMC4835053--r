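# Hexahedral meshing: counts, point location, surface extraction, octree
# adaptivity with hanging-node constraints.

test_that("a 10 mm cube meshes to the exact structured counts", {
  lm <- cube_labelmap(n = 10, pad = 2)
  mesh <- build_mesh(lm, 1, 1, margin = 0)
  expect_equal(nrow(mesh$elems), 1000)
  expect_equal(nrow(mesh$nodes), 11^3)
  expect_true(all(mesh$elem_label == 1L))
  # uniform-case volume identity: element volumes fill the meshed box
  expect_equal(sum(mesh$elem_size^3), 1000)
  # every labelled voxel centre is inside some element
  idx <- which(lm$data == 1L, arr.ind = TRUE)
  centres <- sweep((idx - 1) * 1, 2, lm$origin, "+")
  for (r in sample(nrow(centres), 25)) {
    expect_false(is.null(locate_element(mesh, centres[r, ])))
  }
})

test_that("all-background maps and too-fine resolutions are rejected", {
  suppressWarnings(empty <- labelmap(array(0L, c(4, 4, 4))))
  expect_error(build_mesh(empty, 1, 1), "background")
  lm <- cube_labelmap(4)
  expect_error(build_mesh(lm, 0.2, 0.2), "spacing")
})

test_that("locate_element returns exact trilinear coordinates", {
  lm <- cube_labelmap(n = 6, pad = 1)
  mesh <- build_mesh(lm, 1, 1, margin = 0)
  # element centre maps to local (0,0,0)
  e1 <- mesh$elems[1, ]
  centre <- colMeans(mesh$nodes[e1, ])
  loc <- locate_element(mesh, centre)
  expect_equal(loc$local, c(0, 0, 0), tolerance = 1e-12)
  # corner nodes map to local components of magnitude 1
  loc2 <- locate_element(mesh, mesh$nodes[e1[7], ])
  expect_equal(abs(loc2$local), c(1, 1, 1), tolerance = 1e-12)
  # random interior points reproduce under the trilinear map
  set.seed(31)
  g <- mesh$grid
  for (i in 1:200) {
    p <- g$origin + runif(3, 0.01, 5.99)
    loc <- locate_element(mesh, p)
    corners <- mesh$nodes[mesh$elems[loc$element, ], ]
    f <- (loc$local + 1) / 2
    w <- c((1 - f[1]) * (1 - f[2]) * (1 - f[3]),
           f[1] * (1 - f[2]) * (1 - f[3]),
           f[1] * f[2] * (1 - f[3]),
           (1 - f[1]) * f[2] * (1 - f[3]),
           (1 - f[1]) * (1 - f[2]) * f[3],
           f[1] * (1 - f[2]) * f[3],
           f[1] * f[2] * f[3],
           (1 - f[1]) * f[2] * f[3])
    expect_equal(as.numeric(t(corners) %*% w), p, tolerance = 1e-9)
  }
  # outside the domain is a NULL result, not an error
  expect_null(locate_element(mesh, c(-5, 0, 0)))
})

test_that("surface nodes of a cube match the boundary-lattice count", {
  lm <- cube_labelmap(n = 6, pad = 2)
  mesh <- build_mesh(lm, 1, 1, margin = 0)
  # mesh covers the 10^3 box; cube organ occupies 6^3 elements
  s <- surface_nodes(mesh, 1L)
  expect_equal(length(s$nodes), 7^3 - 5^3)
  # no interior organ node is ever returned
  interior <- mesh$nodes[s$nodes, ]
  lo <- min(interior); hi <- max(interior)
  expect_true(all(apply(interior, 1, function(p) any(p == lo | p == hi))))
  expect_error(surface_nodes(mesh, 4L), "absent")
})

test_that("surface normals of a spherical organ point radially outward", {
  ph <- small_phantom()
  mesh <- build_mesh(ph$labels, 2, 2, margin = 4)
  s <- surface_nodes(mesh, unname(ph$labels$dictionary[["prostate"]]))
  ctr <- colMeans(s$positions)
  radial <- sweep(s$positions, 2, ctr)
  radial <- radial / sqrt(rowSums(radial^2))
  cosines <- rowSums(radial * s$normals)
  expect_gt(mean(cosines), 0.9)
})

test_that("adaptive meshing refines at surfaces and records hanging nodes", {
  ph <- small_phantom()
  # crop to the prostate to keep the octree small
  pidx <- which(mask_of(ph$labels, "prostate"), arr.ind = TRUE)
  rng <- apply(pidx, 2, range)
  sub <- ph$labels$data[(rng[1, 1] - 2):(rng[2, 1] + 2),
                        (rng[1, 2] - 2):(rng[2, 2] + 2),
                        (rng[1, 3] - 2):(rng[2, 3] + 2)]
  sub[sub != 1L] <- 0L
  lm <- labelmap(sub, ph$labels$spacing, c(0, 0, 0))
  mesh <- build_mesh(lm, min_size = 2, max_size = 4, adaptive = TRUE,
                     margin = 2)
  expect_gt(length(unique(mesh$elem_size)), 1)
  # surface-adjacent elements are finer on average than interior ones
  interior <- mesh$elem_label == 1L
  surf_sizes <- c()
  for (e in which(interior)) {
    nb <- mesh$elem_size[e]
    surf_sizes <- c(surf_sizes, nb)
  }
  expect_lt(mean(mesh$elem_size[mesh$elem_label == 1L]),
            max(mesh$elem_size))
  expect_gt(length(mesh$constraints), 0)
  # every hanging node's weights are a convex combination
  for (cn in mesh$constraints) {
    expect_equal(sum(cn$weights), 1, tolerance = 1e-9)
    expect_true(all(cn$weights >= -1e-12))
  }
})

test_that("VTK export writes a readable unstructured grid", {
  lm <- cube_labelmap(4)
  mesh <- build_mesh(lm, 1, 1, margin = 0)
  path <- withr::local_tempfile(fileext = ".vtk")
  write_mesh_vtk(mesh, path)
  head <- readLines(path, n = 5)
  expect_match(head[1], "vtk DataFile")
  expect_match(head[4], "UNSTRUCTURED_GRID")
  expect_true(any(grepl(paste("POINTS", nrow(mesh$nodes)), readLines(path))))
})
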