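# Linear-elastic FEM: element matrices, assembly, loads, constrained solve.

test_that("single-element stiffness has the rigid-body null space and scalings", {
  Ke <- femablate:::hex_element_stiffness(1, material_params(30, 0.45))
  expect_equal(dim(Ke), c(24L, 24L))
  expect_equal(max(abs(Ke - t(Ke))), 0)
  tr <- rep(c(1, -2, 0.5), 8)
  expect_lt(max(abs(Ke %*% tr)), 1e-10)
  Ke2 <- femablate:::hex_element_stiffness(1, material_params(60, 0.45))
  expect_equal(Ke2, 2 * Ke)
  # edge-length scaling is linear for elasticity
  Ke_h <- femablate:::hex_element_stiffness(2.5, material_params(30, 0.45))
  expect_equal(Ke_h, 2.5 * Ke)
})

test_that("element stiffness matches a high-order quadrature oracle", {
  nu <- 0.45
  # independent oracle: direct Gauss integration of B' C B at 4^3 points,
  # assembled with its own shape-function derivatives
  C <- local({
    E <- 1
    lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
    mu <- E / (2 * (1 + nu))
    M <- diag(c(rep(2 * mu, 3), rep(mu, 3)))
    M[1:3, 1:3] <- M[1:3, 1:3] + lam
    M
  })
  off <- 2 * femablate:::hex_corner_offsets() - 1
  gp <- list(x = c(-sqrt(3 / 7 + 2 / 7 * sqrt(6 / 5)),
                   -sqrt(3 / 7 - 2 / 7 * sqrt(6 / 5)),
                   sqrt(3 / 7 - 2 / 7 * sqrt(6 / 5)),
                   sqrt(3 / 7 + 2 / 7 * sqrt(6 / 5))),
             w = c((18 - sqrt(30)) / 36, (18 + sqrt(30)) / 36,
                   (18 + sqrt(30)) / 36, (18 - sqrt(30)) / 36))
  Ko <- matrix(0, 24, 24)
  for (a in 1:4) for (b in 1:4) for (cc in 1:4) {
    xi <- gp$x[a]; eta <- gp$x[b]; zeta <- gp$x[cc]
    dN <- cbind(off[, 1] * (1 + off[, 2] * eta) * (1 + off[, 3] * zeta),
                off[, 2] * (1 + off[, 1] * xi) * (1 + off[, 3] * zeta),
                off[, 3] * (1 + off[, 1] * xi) * (1 + off[, 2] * eta)) / 8
    dNdx <- dN * 2
    B <- matrix(0, 6, 24)
    ix <- 3 * (1:8) - 2
    B[1, ix] <- dNdx[, 1]; B[2, ix + 1] <- dNdx[, 2]; B[3, ix + 2] <- dNdx[, 3]
    B[4, ix] <- dNdx[, 2]; B[4, ix + 1] <- dNdx[, 1]
    B[5, ix + 1] <- dNdx[, 3]; B[5, ix + 2] <- dNdx[, 2]
    B[6, ix] <- dNdx[, 3]; B[6, ix + 2] <- dNdx[, 1]
    Ko <- Ko + gp$w[a] * gp$w[b] * gp$w[cc] / 8 * t(B) %*% C %*% B
  }
  Ke <- femablate:::hex_element_stiffness(1, material_params(1, nu))
  expect_lt(max(abs(Ke - Ko)) / max(abs(Ko)), 1e-6)
})

test_that("assembled stiffness annihilates rigid translations", {
  lm <- cube_labelmap(4, pad = 1)
  mesh <- build_mesh(lm, 1, 1, margin = 0)
  K <- assemble_stiffness(mesh, material_params(30, 0.45))
  n <- nrow(mesh$nodes)
  tr <- rep(c(1, 2, 3), n)
  expect_lt(max(abs(K %*% tr)), 1e-8)
  expect_lt(max(abs(K - Matrix::t(K))), 1e-8)
})

test_that("the patch test passes: uniform boundary displacement, uniform field", {
  lm <- cube_labelmap(8, pad = 1)
  mesh <- build_mesh(lm, 1, 1, margin = 0)
  K <- assemble_stiffness(mesh, material_params(30, 0.45))
  bn <- femablate:::mesh_boundary_nodes(mesh)
  u0 <- c(1, -2, 0.5)
  disp <- matrix(u0, length(bn), 3, byrow = TRUE)
  u <- femablate:::solve_fem(mesh, material_params(30, 0.45),
                             dirichlet_nodes = bn, dirichlet_disp = disp,
                             K = K, tol = 1e-12)
  U <- matrix(u, ncol = 3, byrow = TRUE)
  expect_lt(max(abs(sweep(U, 2, u0))), 1e-8)
})

test_that("a uniaxial bar recovers Hooke's law within 1 percent at nu ~ 0", {
  bar <- array(0L, c(12, 3, 3)); bar[2:11, 2, 2] <- 1L
  lm <- labelmap(bar, c(1, 1, 1), c(0.5, 0.5, 0.5))
  mesh <- build_mesh(lm, 1, 1, margin = 0)
  mat <- material_params(30, 1e-9)
  K <- assemble_stiffness(mesh, mat)
  n <- nrow(mesh$nodes)
  xpos <- mesh$nodes[, 1]
  left <- which(abs(xpos - min(xpos)) < 1e-9)
  right <- which(abs(xpos - max(xpos)) < 1e-9)
  F_ax <- 5
  F <- numeric(3 * n)
  F[3 * (right - 1) + 1] <- F_ax / length(right)
  fd <- as.vector(outer(1:3, 3 * (left - 1), "+"))
  sys <- elastic_system(K, F, fd, numeric(length(fd)))
  u <- solve_displacements(sys, tol = 1e-10)
  tip <- mean(matrix(u, ncol = 3, byrow = TRUE)[right, 1])
  expect_lt(abs(tip - F_ax * 10 / (30 * 1)) / (F_ax * 10 / 30), 0.01)
})

test_that("BiCGStab matches the dense direct oracle and is linear in the load", {
  lm <- cube_labelmap(3, pad = 2)
  mesh <- build_mesh(lm, 1, 1, margin = 0)
  K <- assemble_stiffness(mesh, material_params(30, 0.45))
  set.seed(41)
  F <- rnorm(3 * nrow(mesh$nodes))
  bn <- femablate:::mesh_boundary_nodes(mesh)
  fd <- as.vector(outer(1:3, 3 * (bn - 1), "+"))
  sys <- elastic_system(K, F, fd, numeric(length(fd)))
  u_it <- solve_displacements(sys, tol = 1e-10)
  u_dir <- solve_displacements(sys, method = "direct")
  expect_lt(max(abs(u_it - u_dir)) / max(abs(u_dir)), 1e-6)
  # zero load, homogeneous constraints: exactly zero
  sys0 <- elastic_system(K, numeric(length(F)), fd, numeric(length(fd)))
  expect_equal(max(abs(solve_displacements(sys0))), 0)
  # linearity
  sys2 <- elastic_system(K, 2 * F, fd, numeric(length(fd)))
  u2 <- solve_displacements(sys2, tol = 1e-10)
  expect_equal(u2, 2 * u_it, tolerance = 1e-6, ignore_attr = TRUE)
  # a system without constraints is refused
  expect_error(solve_displacements(elastic_system(K, F)), "singular")
})

test_that("a mirror-symmetric load yields a mirror-symmetric solution", {
  lm <- cube_labelmap(6, pad = 1)
  mesh <- build_mesh(lm, 1, 1, margin = 0)
  mat <- material_params(30, 0.45)
  K <- assemble_stiffness(mesh, mat)
  n <- nrow(mesh$nodes)
  # z-directed point load at the centre of the box: symmetric in x about the
  # mid-plane
  ctr <- colMeans(mesh$nodes)
  centre_node <- which.min(rowSums(sweep(mesh$nodes, 2, ctr)^2))
  F <- numeric(3 * n)
  F[3 * (centre_node - 1) + 3] <- 10
  bn <- femablate:::mesh_boundary_nodes(mesh)
  fd <- as.vector(outer(1:3, 3 * (bn - 1), "+"))
  u <- solve_displacements(elastic_system(K, F, fd, numeric(length(fd))),
                           tol = 1e-10)
  U <- matrix(u, ncol = 3, byrow = TRUE)
  # mirror each node across the x mid-plane and compare uz
  mirrored <- mesh$nodes
  mirrored[, 1] <- 2 * ctr[1] - mirrored[, 1]
  m_id <- femablate:::.cpp_nearest_index(mirrored, mesh$nodes)
  expect_lt(max(abs(U[, 3] - U[m_id, 3])), 1e-7)
  expect_lt(max(abs(U[, 1] + U[m_id, 1])), 1e-7)
})

test_that("prescribed-displacement solutions are invariant to Young's modulus", {
  ph <- desk_phantom()
  dd <- desk_deformed(1)
  ctl <- fem_control(load_mode = "prescribed_displacement",
                     organ_outer_iters = 1, t3_iters = 1)
  r30 <- remove_organ_deformation(ph$labels, dd$labels, dd$image,
                                  material_params(30, 0.45), ctl)
  r300 <- remove_organ_deformation(ph$labels, dd$labels, dd$image,
                                   material_params(300, 0.45), ctl)
  expect_lt(max(abs(r30$field$data - r300$field$data)), 1e-4)
})

test_that("surface loads use symmetric closest-point matching with gating", {
  ph <- small_phantom()
  mesh <- build_mesh(ph$labels, 2, 2, margin = 4)
  # identical surfaces: zero displacement everywhere
  load <- build_surface_load(mesh, ph$labels, "prostate", ph$labels,
                             "prostate")
  expect_lt(max(abs(load$disp)), 2)  # staircase-to-cloud quantisation only
  expect_lt(median(sqrt(rowSums(load$disp^2))), 1)
  # translated convex target: median displacement recovers the translation
  shifted <- ph$labels
  shifted$data <- array(0L, dim(ph$labels$data))
  pro <- which(mask_of(ph$labels, "prostate"), arr.ind = TRUE)
  pro_t <- pro; pro_t[, 1] <- pro_t[, 1] + 3L
  shifted$data[pro_t] <- 1L
  load2 <- build_surface_load(mesh, ph$labels, "prostate", shifted, "prostate")
  med <- apply(load2$disp, 2, median)
  expect_equal(med, c(3, 0, 0), tolerance = 0.5)
  # an empty target surface errors; distant surfaces are gated with a warning
  suppressWarnings(empty <- labelmap(array(0L, dim(ph$labels$data)),
                                     ph$labels$spacing, ph$labels$origin))
  expect_error(build_surface_load(mesh, ph$labels, "prostate", empty,
                                  "prostate"), "empty")
})
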