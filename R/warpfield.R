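# Dense displacement fields: voxel-level realisation of the FEM transforms,
# backward warping, composition and numeric inversion.

# Sample a vol3d at arbitrary world points (n x 3), trilinear or nearest,
# with a fill value outside the volume. Vectorised.
sample_volume <- function(img, p, interp = c("linear", "nearest"), fill = 0) {
  interp <- match.arg(interp)
  d <- grid_dims(img)
  idx <- world_to_index(img, p)
  n <- nrow(p)
  out <- rep(as.numeric(fill), n)
  if (interp == "nearest") {
    ri <- round(idx)
    ok <- ri[, 1] >= 1 & ri[, 1] <= d[1] & ri[, 2] >= 1 & ri[, 2] <= d[2] &
      ri[, 3] >= 1 & ri[, 3] <= d[3]
    lin <- ri[ok, 1] + (ri[ok, 2] - 1) * d[1] + (ri[ok, 3] - 1) * d[1] * d[2]
    out[ok] <- img$data[lin]
    return(out)
  }
  ok <- idx[, 1] >= 1 & idx[, 1] <= d[1] & idx[, 2] >= 1 & idx[, 2] <= d[2] &
    idx[, 3] >= 1 & idx[, 3] <= d[3]
  if (!any(ok)) return(out)
  ix <- idx[ok, , drop = FALSE]
  i0 <- pmin(floor(ix[, 1]), d[1] - 1); fx <- ix[, 1] - i0
  j0 <- pmin(floor(ix[, 2]), d[2] - 1); fy <- ix[, 2] - j0
  k0 <- pmin(floor(ix[, 3]), d[3] - 1); fz <- ix[, 3] - k0
  s1 <- d[1]; s2 <- d[1] * d[2]
  base <- i0 + (j0 - 1) * s1 + (k0 - 1) * s2
  v000 <- img$data[base];           v100 <- img$data[base + 1]
  v010 <- img$data[base + s1];      v110 <- img$data[base + 1 + s1]
  v001 <- img$data[base + s2];      v101 <- img$data[base + 1 + s2]
  v011 <- img$data[base + s1 + s2]; v111 <- img$data[base + 1 + s1 + s2]
  c00 <- v000 * (1 - fx) + v100 * fx
  c10 <- v010 * (1 - fx) + v110 * fx
  c01 <- v001 * (1 - fx) + v101 * fx
  c11 <- v011 * (1 - fx) + v111 * fx
  out[ok] <- (c00 * (1 - fy) + c10 * fy) * (1 - fz) +
    (c01 * (1 - fy) + c11 * fy) * fz
  out
}

# Sample a dispfield at world points, returning an n x 3 matrix (linear
# interpolation per component, zero outside).
sample_field <- function(field, p) {
  comp <- function(k) {
    v <- list(data = field$data[, , , k], spacing = field$spacing,
              origin = field$origin)
    sample_volume(v, p, interp = "linear", fill = 0)
  }
  cbind(comp(1), comp(2), comp(3))
}

#' Interpolate nodal FEM displacements to a dense voxel field
#'
#' Each voxel centre is located inside its containing hexahedral element and
#' the eight corner-node displacements are combined. The default
#' `"trilinear"` scheme uses the element shape functions (the FEM-consistent
#' choice). `"as_printed"` weights each corner by its Euclidean distance from
#' the voxel (normalised) — the literal distance-weighting variant, retained
#' for auditing; `"inverse_distance"` weights by reciprocal distance. Voxels
#' outside the mesh receive zero displacement.
#'
#' @param mesh a [build_mesh()] result.
#' @param U nodal displacement vector of length `3 * N` (or an `N x 3`
#'   matrix), mm.
#' @param grid a [vol3d()] (or any object with grid geometry) defining the
#'   output voxel grid.
#' @param scheme interpolation scheme, see above.
#' @return A [dispfield()] on the geometry of `grid`.
#' @export
interpolate_displacements <- function(mesh, U, grid,
                                      scheme = c("trilinear", "as_printed",
                                                 "inverse_distance")) {
  scheme <- match.arg(scheme)
  Un <- nodal_matrix(mesh, U)
  d <- grid_dims(grid)
  p <- voxel_centers(grid)
  disp <- interp_nodal_at(mesh, Un, p, scheme)
  dispfield(array(disp, dim = c(d, 3L)), grid$spacing, grid$origin)
}

# Interpolate nodal values (N x 3) at arbitrary world points; zero outside
# the mesh. Vectorised for the uniform structured mesh, per-point otherwise.
interp_nodal_at <- function(mesh, Un, p,
                            scheme = c("trilinear", "as_printed",
                                       "inverse_distance")) {
  scheme <- match.arg(scheme)
  disp <- matrix(0, nrow(p), 3)
  if (isTRUE(mesh$uniform)) {
    g <- mesh$grid
    t3 <- cbind((p[, 1] - g$origin[1]) / g$h,
                (p[, 2] - g$origin[2]) / g$h,
                (p[, 3] - g$origin[3]) / g$h)
    e <- floor(t3)
    # points exactly on a shared face belong to the lower element
    # (matches locate_element), which also keeps the mesh's upper
    # boundary inside the domain
    for (ax in 1:3) {
      onface <- t3[, ax] == e[, ax] & e[, ax] > 0
      e[onface, ax] <- e[onface, ax] - 1
    }
    ok <- e[, 1] >= 0 & e[, 1] < g$ndiv[1] & e[, 2] >= 0 & e[, 2] < g$ndiv[2] &
      e[, 3] >= 0 & e[, 3] < g$ndiv[3]
    if (any(ok)) {
      e <- e[ok, , drop = FALSE]
      # local coordinates in [0,1]^3 within the cell
      fx <- t3[ok, 1] - e[, 1]
      fy <- t3[ok, 2] - e[, 2]
      fz <- t3[ok, 3] - e[, 3]
      nx1 <- g$ndiv[1] + 1L; ny1 <- g$ndiv[2] + 1L
      n000 <- (e[, 1] + 1L) + e[, 2] * nx1 + e[, 3] * nx1 * ny1
      corner_off <- list(c(0L, 0L, 0L), c(1L, 0L, 0L), c(1L, 1L, 0L),
                         c(0L, 1L, 0L), c(0L, 0L, 1L), c(1L, 0L, 1L),
                         c(1L, 1L, 1L), c(0L, 1L, 1L))
      nodes8 <- vapply(corner_off, function(o)
        n000 + o[1] + o[2] * nx1 + o[3] * nx1 * ny1, numeric(length(n000)))
      if (!is.matrix(nodes8)) nodes8 <- matrix(nodes8, nrow = 1)
      W <- interp_weights(scheme, fx, fy, fz, g$h)
      acc <- matrix(0, length(n000), 3)
      for (cn in 1:8) {
        acc <- acc + W[, cn] * Un[nodes8[, cn], , drop = FALSE]
      }
      disp[ok, ] <- acc
    }
  } else {
    for (v in seq_len(nrow(p))) {
      loc <- locate_element(mesh, p[v, ])
      if (is.null(loc)) next
      fx <- (loc$local[1] + 1) / 2; fy <- (loc$local[2] + 1) / 2
      fz <- (loc$local[3] + 1) / 2
      W <- interp_weights(scheme, fx, fy, fz, mesh$elem_size[loc$element])
      nodes <- mesh$elems[loc$element, ]
      disp[v, ] <- colSums(as.numeric(W) * Un[nodes, , drop = FALSE])
    }
  }
  disp
}

# Corner weights for a point at fractional cell coordinates (fx,fy,fz) in
# [0,1]^3 of a cube of side h, in the package's corner ordering.
interp_weights <- function(scheme, fx, fy, fz, h) {
  sx <- list(1 - fx, fx, fx, 1 - fx, 1 - fx, fx, fx, 1 - fx)
  sy <- list(1 - fy, 1 - fy, fy, fy, 1 - fy, 1 - fy, fy, fy)
  sz <- list(1 - fz, 1 - fz, 1 - fz, 1 - fz, fz, fz, fz, fz)
  if (scheme == "trilinear") {
    W <- vapply(1:8, function(cn) sx[[cn]] * sy[[cn]] * sz[[cn]],
                numeric(length(fx)))
  } else {
    # distance from the point to each corner, in cell units (h cancels on
    # normalisation)
    W <- vapply(1:8, function(cn) {
      dx <- fx - c(0, 1, 1, 0, 0, 1, 1, 0)[cn]
      dy <- fy - c(0, 0, 1, 1, 0, 0, 1, 1)[cn]
      dz <- fz - c(0, 0, 0, 0, 1, 1, 1, 1)[cn]
      sqrt(dx^2 + dy^2 + dz^2)
    }, numeric(length(fx)))
    if (scheme == "inverse_distance") W <- 1 / pmax(W, 1e-9)
  }
  if (!is.matrix(W)) W <- matrix(W, nrow = 1)
  W / rowSums(W)
}

nodal_matrix <- function(mesh, U) {
  n <- nrow(mesh$nodes)
  if (is.matrix(U)) {
    stopifnot(nrow(U) == n, ncol(U) == 3)
    U
  } else {
    stopifnot(length(U) == 3 * n)
    matrix(U, ncol = 3, byrow = TRUE)
  }
}

#' Warp an image with a dense displacement field
#'
#' Backward-warping convention: the output voxel at centre `c` samples the
#' input at `c + d(c)`. Out-of-volume samples receive `fill`.
#'
#' @param img a [vol3d()] or [labelmap()] on the same grid as `field`.
#' @param field a [dispfield()].
#' @param interp `"linear"` or `"nearest"`; label maps are always warped with
#'   nearest-neighbour.
#' @param fill fill value for samples outside the input volume.
#' @return Warped object of the same class as `img`.
#' @export
warp_image <- function(img, field, interp = c("linear", "nearest"), fill = 0) {
  interp <- match.arg(interp)
  stop_grid_mismatch(img, field, "image and field")
  if (inherits(img, "labelmap")) interp <- "nearest"
  p <- voxel_centers(img) + matrix(field$data, ncol = 3)
  vals <- sample_volume(img, p, interp = interp, fill = fill)
  d <- grid_dims(img)
  if (inherits(img, "labelmap")) {
    labelmap(array(as.integer(vals), dim = d), img$spacing, img$origin,
             img$dictionary)
  } else {
    vol3d(array(vals, dim = d), img$spacing, img$origin)
  }
}

#' Compose displacement fields
#'
#' Functional composition by resampling, in warp-application order: warping
#' an image with `compose_fields(list(f1, f2))` matches warping it with `f1`
#' and then warping the result with `f2`, within resampling tolerance. In
#' backward-warp field algebra the composed field is
#' `d(c) = d2(c) + d1(c + d2(c))`.
#'
#' @param fields list of [dispfield()] objects on a shared grid, in the
#'   order the warps are applied to the image.
#' @return A single [dispfield()].
#' @export
compose_fields <- function(fields) {
  if (!length(fields)) stop("empty field list")
  acc <- fields[[length(fields)]]
  if (length(fields) == 1L) return(acc)
  p0 <- voxel_centers(acc)
  d <- grid_dims(acc)
  for (b in rev(fields)[-1]) {
    stop_grid_mismatch(acc, b, "composed fields")
    da <- matrix(acc$data, ncol = 3)
    db <- sample_field(b, p0 + da)
    acc <- dispfield(array(da + db, dim = c(d, 3L)), acc$spacing, acc$origin)
  }
  acc
}

#' Numerically invert a displacement field
#'
#' Fixed-point iteration `d_inv(c) <- -d(c + d_inv(c))`, at most `max_iter`
#' sweeps or until the largest update is below `tol` mm. Utility only: the
#' pipeline's organ-deformation removal solves directly in the inverse
#' direction and never inverts a field numerically.
#'
#' @param field a [dispfield()].
#' @param max_iter maximum fixed-point sweeps.
#' @param tol convergence threshold on the max update, mm.
#' @return The approximate inverse [dispfield()].
#' @export
invert_field <- function(field, max_iter = 20L, tol = 0.01) {
  p0 <- voxel_centers(field)
  d <- grid_dims(field)
  inv <- matrix(0, nrow(p0), 3)
  for (it in seq_len(max_iter)) {
    new <- -sample_field(field, p0 + inv)
    delta <- max(abs(new - inv))
    inv <- new
    if (delta < tol) break
  }
  dispfield(array(inv, dim = c(d, 3L)), field$spacing, field$origin)
}

#' Deformation-magnitude heatmap
#'
#' Per-voxel Euclidean norm of the displacement, in mm — the quantity shown
#' in deformation heatmaps of treatment-induced shape change.
#'
#' @param field a [dispfield()].
#' @return A [vol3d()] of displacement magnitudes.
#' @export
magnitude_map <- function(field) {
  m <- sqrt(field$data[, , , 1]^2 + field$data[, , , 2]^2 +
              field$data[, , , 3]^2)
  vol3d(m, field$spacing, field$origin)
}
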