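# Linear-elastic FEM: stiffness assembly for trilinear hexahedra, surface
# loads from organ-surface correspondences, and the constrained solve.
#
# Degrees of freedom are node-major: node n owns DOFs 3(n-1)+1..3(n-1)+3.

#' Material parameters for the homogeneous soft-tissue model
#'
#' Young's modulus defaults to 30 kPa, the soft-tissue operating point;
#' Poisson's ratio defaults to 0.45 (near-incompressible soft tissue,
#' standard in the prostate-FEM literature — the value is a package choice).
#'
#' @param youngs_modulus Young's modulus in kPa, > 0.
#' @param poisson_ratio Poisson's ratio, in (0, 0.5).
#' @return An object of class `material_params`.
#' @export
material_params <- function(youngs_modulus = 30, poisson_ratio = 0.45) {
  if (!is.numeric(youngs_modulus) || youngs_modulus <= 0)
    stop("youngs_modulus must be > 0 (kPa)")
  if (!is.numeric(poisson_ratio) || poisson_ratio <= 0 || poisson_ratio >= 0.5)
    stop("poisson_ratio must lie strictly inside (0, 0.5)")
  structure(list(youngs_modulus = youngs_modulus,
                 poisson_ratio = poisson_ratio),
            class = "material_params")
}

# 24 x 24 stiffness of a cube trilinear hexahedron with edge h, unit Young's
# modulus and the given Poisson ratio, by Gauss quadrature of B' C B.
# For elasticity the element matrix scales linearly with both E and h.
hex_element_stiffness <- function(h, material, n_gauss = 2) {
  Ke <- hex_unit_stiffness(material$poisson_ratio, n_gauss)
  material$youngs_modulus * h * Ke
}

hex_unit_stiffness <- function(nu, n_gauss = 2) {
  cache_key <- sprintf("nu%.12g_g%d", nu, n_gauss)
  hit <- .fem_cache[[cache_key]]
  if (!is.null(hit)) return(hit)
  C <- isotropic_elasticity_matrix(1, nu)
  gp <- gauss_points(n_gauss)
  Ke <- matrix(0, 24, 24)
  off <- 2 * hex_corner_offsets() - 1  # corner signs in [-1,1]^3
  for (a in seq_along(gp$x)) for (b in seq_along(gp$x)) for (cix in seq_along(gp$x)) {
    xi <- gp$x[a]; eta <- gp$x[b]; zeta <- gp$x[cix]
    w <- gp$w[a] * gp$w[b] * gp$w[cix]
    # shape-function gradients wrt local coords
    dN <- cbind(off[, 1] * (1 + off[, 2] * eta) * (1 + off[, 3] * zeta),
                off[, 2] * (1 + off[, 1] * xi) * (1 + off[, 3] * zeta),
                off[, 3] * (1 + off[, 1] * xi) * (1 + off[, 2] * eta)) / 8
    # for a cube of edge h: J = (h/2) I; dN/dx = dN/dxi * 2/h; detJ = (h/2)^3
    # with h = 1 here, the element matrix scales as E * h overall
    dNdx <- dN * 2
    B <- matrix(0, 6, 24)
    ix <- 3 * (1:8) - 2
    B[1, ix] <- dNdx[, 1]; B[2, ix + 1] <- dNdx[, 2]; B[3, ix + 2] <- dNdx[, 3]
    B[4, ix] <- dNdx[, 2]; B[4, ix + 1] <- dNdx[, 1]
    B[5, ix + 1] <- dNdx[, 3]; B[5, ix + 2] <- dNdx[, 2]
    B[6, ix] <- dNdx[, 3]; B[6, ix + 2] <- dNdx[, 1]
    Ke <- Ke + w * (1 / 8) * t(B) %*% C %*% B
  }
  Ke <- (Ke + t(Ke)) / 2
  .fem_cache[[cache_key]] <- Ke
  Ke
}

.fem_cache <- new.env(parent = emptyenv())

isotropic_elasticity_matrix <- function(E, nu) {
  lambda <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  C <- diag(c(rep(2 * mu, 3), rep(mu, 3)))
  C[1:3, 1:3] <- C[1:3, 1:3] + lambda
  C
}

gauss_points <- function(n) {
  switch(as.character(n),
         "1" = list(x = 0, w = 2),
         "2" = list(x = c(-1, 1) / sqrt(3), w = c(1, 1)),
         "3" = list(x = c(-sqrt(3 / 5), 0, sqrt(3 / 5)),
                    w = c(5, 8, 5) / 9),
         "4" = {
           a <- sqrt(3 / 7 - 2 / 7 * sqrt(6 / 5))
           b <- sqrt(3 / 7 + 2 / 7 * sqrt(6 / 5))
           wa <- (18 + sqrt(30)) / 36; wb <- (18 - sqrt(30)) / 36
           list(x = c(-b, -a, a, b), w = c(wb, wa, wa, wb))
         },
         stop("unsupported quadrature order ", n))
}

#' Assemble the global stiffness matrix
#'
#' Standard isotropic linear elasticity from trilinear hexahedral elements
#' with 2x2x2 Gauss quadrature. The result is sparse, symmetric, and
#' annihilates rigid translations (before constraints).
#'
#' @param mesh a [build_mesh()] result.
#' @param material a [material_params()].
#' @return A `3N x 3N` sparse symmetric `Matrix::dgCMatrix` (kPa mm).
#' @export
assemble_stiffness <- function(mesh, material) {
  if (any(mesh$elem_size <= 0)) stop("element ", which(mesh$elem_size <= 0)[1],
                                     " has non-positive size")
  n <- nrow(mesh$nodes)
  Ke1 <- hex_unit_stiffness(material$poisson_ratio)
  # element DOF map: E x 24, node-major DOFs
  D <- matrix(0L, nrow(mesh$elems), 24L)
  for (cn in 1:8) {
    base <- 3L * (mesh$elems[, cn] - 1L)
    D[, 3 * cn - 2] <- base + 1L
    D[, 3 * cn - 1] <- base + 2L
    D[, 3 * cn] <- base + 3L
  }
  ii <- D[, rep(1:24, times = 24), drop = FALSE]
  jj <- D[, rep(1:24, each = 24), drop = FALSE]
  scale <- material$youngs_modulus * mesh$elem_size
  xx <- outer(scale, as.vector(Ke1))
  Matrix::sparseMatrix(i = as.vector(ii), j = as.vector(jj), x = as.vector(xx),
                       dims = c(3 * n, 3 * n))
}

#' Elastic system container
#'
#' Bundles the stiffness matrix, force vector and Dirichlet constraints ahead
#' of [solve_displacements()]. Hanging-node constraints (adaptive meshes) are
#' eliminated master-slave inside the solve.
#'
#' @param stiffness sparse `3N x 3N` stiffness matrix.
#' @param forces length-`3N` force vector.
#' @param fixed_dofs integer DOF indices with prescribed displacements.
#' @param fixed_values prescribed displacement values (mm), same length.
#' @param constraints hanging-node constraint list from the mesh.
#' @return An object of class `elastic_system`.
#' @export
elastic_system <- function(stiffness, forces, fixed_dofs = integer(),
                           fixed_values = numeric(length(fixed_dofs)),
                           constraints = list()) {
  stopifnot(nrow(stiffness) == ncol(stiffness),
            length(forces) == nrow(stiffness),
            length(fixed_dofs) == length(fixed_values))
  structure(list(stiffness = stiffness, forces = forces,
                 fixed_dofs = as.integer(fixed_dofs),
                 fixed_values = as.numeric(fixed_values),
                 constraints = constraints),
            class = "elastic_system")
}

#' Solve the constrained elastic system
#'
#' Eliminates hanging-node constraints and Dirichlet DOFs, then solves the
#' reduced system with Jacobi-preconditioned BiCGStab (default) or a dense
#' direct solve (small systems; used as the independent oracle in tests).
#'
#' @param system an [elastic_system()].
#' @param tol relative residual tolerance for BiCGStab.
#' @param max_iter iteration cap; default `10 * 3N` capped at 20000.
#' @param method `"bicgstab"` or `"direct"`.
#' @param x0 optional warm-start displacement vector of length `3N`.
#' @return Length-`3N` displacement vector (mm) with attributes
#'   `iterations` and `relres`.
#' @export
solve_displacements <- function(system, tol = 1e-6, max_iter = NULL,
                                method = c("bicgstab", "direct"), x0 = NULL) {
  method <- match.arg(method)
  K <- system$stiffness
  n <- nrow(K)
  if (is.null(max_iter)) max_iter <- min(10L * n, 20000L)
  Tmat <- constraint_transform(n, system$constraints)
  if (!is.null(Tmat)) {
    Kc <- Matrix::t(Tmat) %*% K %*% Tmat
    Fc <- as.numeric(Matrix::t(Tmat) %*% system$forces)
    master_of <- attr(Tmat, "master_map")
    fixed <- master_of[system$fixed_dofs]
    if (anyNA(fixed)) stop("Dirichlet constraint on a hanging (slave) node")
  } else {
    Kc <- K; Fc <- system$forces
    fixed <- system$fixed_dofs
  }
  nc <- nrow(Kc)
  free <- setdiff(seq_len(nc), fixed)
  if (!length(fixed))
    stop("no Dirichlet constraints: the elastic system is singular")
  uc <- numeric(nc)
  uc[fixed] <- system$fixed_values
  rhs <- Fc[free]
  if (any(system$fixed_values != 0))
    rhs <- rhs - as.numeric(Kc[free, fixed, drop = FALSE] %*%
                              system$fixed_values)
  Kff <- Kc[free, free, drop = FALSE]
  if (method == "direct") {
    if (length(free) > 6000)
      stop("direct dense solve limited to small systems; use bicgstab")
    uf <- solve(as.matrix(Kff), rhs)
    it <- NA_integer_
    relres <- sqrt(sum((rhs - as.numeric(Kff %*% uf))^2)) /
      max(sqrt(sum(rhs^2)), 1e-300)
  } else {
    start <- if (is.null(x0)) numeric(length(free)) else {
      xc <- if (!is.null(Tmat)) x0[attr(Tmat, "master_dofs")] else x0
      xc[free]
    }
    Kff <- methods::as(Kff, "CsparseMatrix")
    res <- .cpp_bicgstab(Kff@p, Kff@i, Kff@x, rhs, start, tol,
                         as.integer(max_iter))
    if (!res$converged && res$relres > 100 * tol)
      stop("BiCGStab failed to converge: relative residual ",
           signif(res$relres, 3), " after ", res$iterations, " iterations")
    uf <- res$x
    it <- res$iterations
    relres <- res$relres
  }
  uc[free] <- uf
  u <- if (!is.null(Tmat)) as.numeric(Tmat %*% uc) else uc
  attr(u, "iterations") <- it
  attr(u, "relres") <- relres
  u
}

# Build the (3N x 3M) master-slave elimination transform for hanging-node
# constraints; NULL when there are none. attr master_map maps full DOF index
# to reduced index (NA for slave DOFs); attr master_dofs lists kept DOFs.
constraint_transform <- function(n, constraints) {
  if (!length(constraints)) return(NULL)
  slave_nodes <- vapply(constraints, `[[`, numeric(1), "node")
  slave_dofs <- as.vector(outer(1:3, 3 * (slave_nodes - 1), "+"))
  master_dofs <- setdiff(seq_len(n), slave_dofs)
  master_map <- rep(NA_integer_, n)
  master_map[master_dofs] <- seq_along(master_dofs)
  ti <- list(); tj <- list(); tx <- list()
  ti[[1]] <- master_dofs
  tj[[1]] <- seq_along(master_dofs)
  tx[[1]] <- rep(1, length(master_dofs))
  k <- 2L
  for (cn in constraints) {
    for (comp in 1:3) {
      sd <- 3 * (cn$node - 1) + comp
      md <- master_map[3 * (cn$masters - 1) + comp]
      if (anyNA(md)) stop("chained hanging-node constraints are not supported")
      ti[[k]] <- rep(sd, length(md)); tj[[k]] <- md; tx[[k]] <- cn$weights
      k <- k + 1L
    }
  }
  Tmat <- Matrix::sparseMatrix(i = unlist(ti), j = unlist(tj), x = unlist(tx),
                               dims = c(n, length(master_dofs)))
  attr(Tmat, "master_map") <- master_map
  attr(Tmat, "master_dofs") <- master_dofs
  Tmat
}

#' Surface loads from organ-surface correspondence
#'
#' For each surface node of the moving organ (on the mesh configuration),
#' computes the displacement to its corresponding point on the target organ
#' surface by symmetric closest-point matching between the node set and the
#' target's boundary-voxel cloud. Correspondences farther than `gating` mm
#' are excluded with a warning. In `prescribed_displacement` mode the
#' displacements become Dirichlet values; in `force` mode they are turned
#' into spring-scaled nodal forces by the solver driver (see
#' [remove_organ_deformation()]).
#'
#' @param mesh mesh built on the moving configuration.
#' @param moving_labels,moving_organ the moving [labelmap()] and organ (used
#'   for the mesh surface node set).
#' @param target_labels,target_organ the target surface.
#' @param mode `"prescribed_displacement"` (default) or `"force"`.
#' @param gating correspondence gating radius, mm.
#' @param node_positions optional current positions of all mesh nodes
#'   (defaults to the rest configuration; iterative drivers pass updated
#'   positions).
#' @return List with `nodes`, `positions`, `disp` (n x 3 mm), `mode`.
#' @export
build_surface_load <- function(mesh, moving_labels, moving_organ,
                               target_labels, target_organ,
                               mode = c("prescribed_displacement", "force"),
                               gating = 20, node_positions = NULL) {
  mode <- match.arg(mode)
  lab <- organ_label_value(moving_labels, moving_organ)
  surf <- surface_nodes(mesh, lab)
  pos <- if (is.null(node_positions)) surf$positions else
    node_positions[surf$nodes, , drop = FALSE]
  target <- surface_voxel_cloud(target_labels, target_organ)
  if (!nrow(target)) stop("target surface for organ '", target_organ,
                          "' is empty")
  # iterated rigid (translation) pre-alignment so coherent organ shifts are
  # captured in full rather than aperture-projected onto surface normals
  shift <- c(0, 0, 0)
  for (it in 1:20) {
    d0 <- closest_point_displacement(sweep(pos, 2, shift, "+"), target,
                                     gating)
    step <- colMeans(d0, na.rm = TRUE)
    if (any(!is.finite(step)) || max(abs(step)) < 0.05) break
    shift <- shift + step
  }
  d <- closest_point_displacement(sweep(pos, 2, shift, "+"), target, gating)
  d <- sweep(d, 2, shift, "+")
  keep <- !is.na(d[, 1])
  if (!all(keep))
    warning(sum(!keep), " surface node(s) exceeded the ", gating,
            " mm gating radius and were excluded")
  list(nodes = surf$nodes[keep], positions = pos[keep, , drop = FALSE],
       disp = d[keep, , drop = FALSE], mode = mode)
}

# Boundary-voxel centres (world mm) of one organ of a label map: voxels of
# the organ with at least one 6-neighbour of a different label.
surface_voxel_cloud <- function(labels, organ) {
  m <- organ_mask(labels, organ)
  d <- dim(m)
  interior <- m
  interior[] <- TRUE
  shift_and <- function(acc, src) acc & src
  pad <- function(along, by) {
    s <- m
    idx <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    src <- idx; dst <- idx
    if (by > 0) { dst[[along]] <- 2:d[along]; src[[along]] <- 1:(d[along] - 1) }
    else { dst[[along]] <- 1:(d[along] - 1); src[[along]] <- 2:d[along] }
    out <- array(FALSE, d)
    out[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
    out
  }
  for (ax in 1:3) for (sgn in c(-1, 1))
    interior <- shift_and(interior, pad(ax, sgn))
  boundary <- m & !interior
  idx <- which(boundary, arr.ind = TRUE)
  out <- sweep((idx - 1) * rep(labels$spacing, each = nrow(idx)), 2,
               labels$origin, "+")
  dimnames(out) <- NULL
  out
}

# Symmetric closest-point correspondence: forward nearest-target match per
# node, averaged with the mean pull of target points whose nearest node it
# is. NA rows mark gated-out nodes.
closest_point_displacement <- function(pos, target, gating) {
  fwd <- .cpp_nearest_index(pos, target)
  d <- target[fwd, , drop = FALSE] - pos
  rev <- .cpp_nearest_index(target, pos)
  pull <- rowsum((target - pos[rev, , drop = FALSE]), rev)
  cnt <- tabulate(rev, nbins = nrow(pos))
  hit <- as.integer(rownames(pull))
  d2 <- d
  d2[hit, ] <- (d[hit, , drop = FALSE] +
                  pull / pmax(cnt[hit], 1L)) / 2
  too_far <- sqrt(rowSums(d2^2)) > gating
  d2[too_far, ] <- NA_real_
  d2
}

# Convenience: assemble + constrain + solve for a mesh with far-field
# (outer-boundary) fixation, optional extra Dirichlet data and nodal forces.
solve_fem <- function(mesh, material, forces = NULL, dirichlet_nodes = NULL,
                      dirichlet_disp = NULL, K = NULL, tol = 1e-6,
                      max_iter = NULL, method = "bicgstab", x0 = NULL,
                      far_field = "all") {
  n <- nrow(mesh$nodes)
  if (is.null(K)) K <- assemble_stiffness(mesh, material)
  F <- numeric(3 * n)
  if (!is.null(forces)) F <- forces
  # explicit Dirichlet data takes precedence over the far-field fixation
  fixed_dofs <- integer(); fixed_values <- numeric()
  if (!is.null(dirichlet_nodes) && length(dirichlet_nodes)) {
    fixed_values <- as.vector(t(dirichlet_disp))  # node-major x,y,z
    fixed_dofs <- as.vector(vapply(dirichlet_nodes, function(nd)
      3 * (nd - 1) + 1:3, numeric(3)))
  }
  outer_nodes <- mesh_boundary_nodes(mesh, far_field)
  odof <- as.vector(outer(1:3, 3 * (outer_nodes - 1), "+"))
  newdof <- !(odof %in% fixed_dofs)
  fixed_dofs <- c(fixed_dofs, odof[newdof])
  fixed_values <- c(fixed_values, numeric(sum(newdof)))
  sys <- elastic_system(K, F, fixed_dofs, fixed_values, mesh$constraints)
  solve_displacements(sys, tol = tol, max_iter = max_iter, method = method,
                      x0 = x0)
}
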