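# Hexahedral meshing of label maps.
#
# The default mesh is a uniform structured grid of cube elements covering the
# bounding box of all labelled organs plus a margin of background elements
# (so far-field Dirichlet fixation is applied away from the organs). An
# octree-style curvature-adaptive mode subdivides surface-intersecting
# elements down to `min_size`, recording hanging-node constraints.
#
# Element corner ordering (VTK hexahedron): offsets within the cell, in cell
# units, are (0,0,0),(1,0,0),(1,1,0),(0,1,0),(0,0,1),(1,0,1),(1,1,1),(0,1,1).

hex_corner_offsets <- function() {
  matrix(c(0, 0, 0, 1, 0, 0, 1, 1, 0, 0, 1, 0,
           0, 0, 1, 1, 0, 1, 1, 1, 1, 0, 1, 1),
         ncol = 3, byrow = TRUE)
}

#' Build a hexahedral mesh from a label map
#'
#' @param labels a [labelmap()] with at least one nonzero voxel.
#' @param min_size,max_size element edge length bounds in mm. The default is
#'   the uniform 1 mm operating point; set `max_size > min_size` with
#'   `adaptive = TRUE` for octree subdivision of surface-intersecting
#'   elements (`max_size` is rounded to `min_size * 2^k`).
#' @param adaptive subdivide elements that straddle organ surfaces.
#' @param margin mm of background elements added around the organ bounding
#'   box.
#' @return An object of class `hexmesh`: `nodes` (N x 3 mm), `elems`
#'   (E x 8 node indices), `elem_label`, `elem_size` (mm), and for adaptive
#'   meshes a `constraints` list of hanging-node linear constraints.
#' @export
build_mesh <- function(labels, min_size = 1, max_size = min_size,
                       adaptive = FALSE, margin = 10) {
  stopifnot(inherits(labels, "labelmap"))
  if (min_size > max_size) stop("min_size must be <= max_size")
  if (min_size < min(labels$spacing) / 2)
    stop("min_size ", min_size, " mm is below half the smallest voxel spacing; ",
         "refine the image grid instead")
  lab_idx <- which(labels$data != 0L, arr.ind = TRUE)
  if (!nrow(lab_idx)) stop("cannot mesh an all-background label map")
  lo <- unname(labels$origin + (apply(lab_idx, 2, min) - 1) * labels$spacing -
                 labels$spacing / 2 - margin)
  hi <- unname(labels$origin + (apply(lab_idx, 2, max) - 1) * labels$spacing +
                 labels$spacing / 2 + margin)
  if (!adaptive || max_size == min_size) {
    build_uniform_mesh(labels, min_size, lo, hi)
  } else {
    build_adaptive_mesh(labels, min_size, max_size, lo, hi)
  }
}

build_uniform_mesh <- function(labels, h, lo, hi) {
  ndiv <- pmax(1L, as.integer(ceiling((hi - lo) / h - 1e-9)))
  nx <- ndiv[1]; ny <- ndiv[2]; nz <- ndiv[3]
  nx1 <- nx + 1L; ny1 <- ny + 1L; nz1 <- nz + 1L
  nodes <- cbind(
    rep(lo[1] + (0:nx) * h, times = ny1 * nz1),
    rep(rep(lo[2] + (0:ny) * h, each = nx1), times = nz1),
    rep(lo[3] + (0:nz) * h, each = nx1 * ny1)
  )
  ei <- rep(0:(nx - 1), times = ny * nz)
  ej <- rep(rep(0:(ny - 1), each = nx), times = nz)
  ek <- rep(0:(nz - 1), each = nx * ny)
  n000 <- (ei + 1L) + ej * nx1 + ek * nx1 * ny1
  off <- hex_corner_offsets()
  elems <- vapply(1:8, function(cn)
    n000 + off[cn, 1] + off[cn, 2] * nx1 + off[cn, 3] * nx1 * ny1,
    numeric(length(n000)))
  storage.mode(elems) <- "integer"
  centers <- cbind(lo[1] + (ei + 0.5) * h, lo[2] + (ej + 0.5) * h,
                   lo[3] + (ek + 0.5) * h)
  elem_label <- majority_label(labels, centers, h)
  structure(list(nodes = nodes, elems = elems, elem_label = elem_label,
                 elem_size = rep(h, nrow(elems)), uniform = TRUE,
                 grid = list(origin = lo, h = h, ndiv = c(nx, ny, nz)),
                 constraints = list(),
                 cache = new.env(parent = emptyenv())),
            class = "hexmesh")
}

# Majority voxel label within each cube element, by sampling a regular
# sub-grid of points per element (exact when the element size is a multiple
# of the voxel spacing and the grids align; a close proxy otherwise).
majority_label <- function(labels, centers, h) {
  s <- max(1L, min(4L, as.integer(round(h / min(labels$spacing)))))
  fr <- ((seq_len(s) - 0.5) / s - 0.5) * h
  votes <- matrix(0L, nrow(centers), 5L)  # labels 0..4
  for (ox in fr) for (oy in fr) for (oz in fr) {
    p <- cbind(centers[, 1] + ox, centers[, 2] + oy, centers[, 3] + oz)
    l <- sample_volume(labels, p, interp = "nearest", fill = 0)
    l <- pmin(pmax(as.integer(l), 0L), 4L)
    votes[cbind(seq_len(nrow(votes)), l + 1L)] <-
      votes[cbind(seq_len(nrow(votes)), l + 1L)] + 1L
  }
  as.integer(max.col(votes, ties.method = "first") - 1L)
}

#' @export
print.hexmesh <- function(x, ...) {
  cat("<hexmesh> ", nrow(x$elems), " hexahedra, ", nrow(x$nodes), " nodes, ",
      "element size ", paste(signif(sort(unique(x$elem_size)), 3),
                             collapse = "/"), " mm",
      if (length(x$constraints)) paste0(", ", length(x$constraints),
                                        " hanging nodes"), "\n", sep = "")
  invisible(x)
}

# ---- adaptive (octree) meshing --------------------------------------------

build_adaptive_mesh <- function(labels, min_size, max_size, lo, hi) {
  nlev <- max(0L, as.integer(round(log2(max_size / min_size))))
  h0 <- min_size * 2^nlev  # snap max_size to a power-of-two multiple
  ndiv0 <- pmax(1L, as.integer(ceiling((hi - lo) / h0 - 1e-9)))
  # leaves: data.frame of (level, i, j, k); cell size = h0 / 2^level
  leaves <- expand.grid(i = 0:(ndiv0[1] - 1), j = 0:(ndiv0[2] - 1),
                        k = 0:(ndiv0[3] - 1))
  leaves$level <- 0L
  subdivided <- new.env(hash = TRUE)
  key <- function(l, i, j, k) paste(l, i, j, k, sep = "_")
  for (lev in 0:(nlev - 1)) {
    h <- h0 / 2^lev
    sel <- leaves$level == lev &
      mixed_cell(labels, lo, h, leaves$i, leaves$j, leaves$k)
    if (!any(sel)) next
    par <- leaves[sel, , drop = FALSE]
    for (r in seq_len(nrow(par)))
      assign(key(par$level[r], par$i[r], par$j[r], par$k[r]), TRUE, subdivided)
    kids <- do.call(rbind, lapply(seq_len(nrow(par)), function(r) {
      o <- hex_corner_offsets()
      data.frame(i = 2L * par$i[r] + o[, 1], j = 2L * par$j[r] + o[, 2],
                 k = 2L * par$k[r] + o[, 3], level = lev + 1L)
    }))
    leaves <- rbind(leaves[!sel, , drop = FALSE], kids)
  }
  # 2:1 balance: a leaf may not neighbour a leaf more than one level finer
  repeat {
    changed <- FALSE
    sizes <- h0 / 2^leaves$level
    centers <- cbind(lo[1] + (leaves$i + 0.5) * sizes,
                     lo[2] + (leaves$j + 0.5) * sizes,
                     lo[3] + (leaves$k + 0.5) * sizes)
    finest <- max(leaves$level)
    for (r in which(leaves$level < finest - 1L)) {
      s <- sizes[r]
      for (dir in 1:6) {
        ax <- (dir + 1) %/% 2; sg <- if (dir %% 2) -1 else 1
        p <- centers[r, ]; p[ax] <- p[ax] + sg * (s / 2 + min_size / 4)
        nb <- octree_locate(leaves, subdivided, lo, h0, p)
        if (!is.null(nb) && leaves$level[nb] > leaves$level[r] + 1L) {
          leaves <- octree_subdivide(leaves, subdivided, r, key)
          changed <- TRUE
          break
        }
      }
      if (changed) break
    }
    if (!changed) break
  }
  finalize_adaptive(labels, leaves, subdivided, lo, h0, min_size)
}

mixed_cell <- function(labels, lo, h, i, j, k) {
  s <- max(2L, min(5L, as.integer(round(h / min(labels$spacing))) + 1L))
  fr <- (seq_len(s) - 0.5) / s * h
  first <- NULL; mixed <- rep(FALSE, length(i))
  for (ox in fr) for (oy in fr) for (oz in fr) {
    p <- cbind(lo[1] + i * h + ox, lo[2] + j * h + oy, lo[3] + k * h + oz)
    l <- sample_volume(labels, p, interp = "nearest", fill = 0)
    if (is.null(first)) first <- l else mixed <- mixed | (l != first)
  }
  mixed
}

octree_subdivide <- function(leaves, subdivided, r, key) {
  assign(key(leaves$level[r], leaves$i[r], leaves$j[r], leaves$k[r]),
         TRUE, subdivided)
  o <- hex_corner_offsets()
  kids <- data.frame(i = 2L * leaves$i[r] + o[, 1], j = 2L * leaves$j[r] + o[, 2],
                     k = 2L * leaves$k[r] + o[, 3], level = leaves$level[r] + 1L)
  rbind(leaves[-r, , drop = FALSE], kids)
}

# Locate the leaf row containing world point p, descending from the coarse
# grid through subdivided cells. NULL when outside the domain.
octree_locate <- function(leaves, subdivided, lo, h0, p) {
  c0 <- floor((p - lo) / h0)
  lev <- 0L; i <- c0[1]; j <- c0[2]; k <- c0[3]
  repeat {
    hit <- which(leaves$level == lev & leaves$i == i & leaves$j == j &
                   leaves$k == k)
    if (length(hit)) return(hit[1])
    if (!exists(paste(lev, i, j, k, sep = "_"), envir = subdivided,
                inherits = FALSE)) return(NULL)
    h <- h0 / 2^(lev + 1)
    ci <- floor((p - lo) / h)
    i <- ci[1]; j <- ci[2]; k <- ci[3]; lev <- lev + 1L
  }
}

finalize_adaptive <- function(labels, leaves, subdivided, lo, h0, min_size) {
  sizes <- h0 / 2^leaves$level
  off <- hex_corner_offsets()
  # node coordinates in integer units of min_size (corners of any leaf are
  # multiples of its own size, hence of min_size)
  unit <- min_size
  corner_keys <- lapply(1:8, function(cn) {
    cbind(round((leaves$i + off[cn, 1]) * sizes / unit),
          round((leaves$j + off[cn, 2]) * sizes / unit),
          round((leaves$k + off[cn, 3]) * sizes / unit))
  })
  allk <- do.call(rbind, corner_keys)
  keys <- paste(allk[, 1], allk[, 2], allk[, 3], sep = "_")
  ukeys <- unique(keys)
  nid <- match(keys, ukeys)
  ucoord <- allk[!duplicated(keys), , drop = FALSE]
  nodes <- sweep(ucoord * unit, 2, lo, "+")
  ne <- nrow(leaves)
  elems <- matrix(nid, nrow = ne, ncol = 8)
  storage.mode(elems) <- "integer"
  centers <- cbind(lo[1] + (leaves$i + 0.5) * sizes,
                   lo[2] + (leaves$j + 0.5) * sizes,
                   lo[3] + (leaves$k + 0.5) * sizes)
  elem_label <- integer(ne)
  for (h in unique(sizes)) {
    sel <- sizes == h
    elem_label[sel] <- majority_label(labels, centers[sel, , drop = FALSE], h)
  }
  mesh <- structure(list(nodes = nodes, elems = elems, elem_label = elem_label,
                         elem_size = sizes, uniform = FALSE,
                         grid = list(origin = lo, h = h0,
                                     ndiv = pmax(1L, as.integer(
                                       ceiling(round((apply(nodes, 2, max) - lo) / h0, 9))))),
                         leaves = leaves, subdivided = subdivided,
                         constraints = list(),
                         cache = new.env(parent = emptyenv())),
                    class = "hexmesh")
  mesh$constraints <- hanging_constraints(mesh)
  mesh
}

# A node is hanging when it lies on the boundary of a coarser leaf without
# being one of that leaf's corners; it is then constrained to the trilinear
# interpolation of the coarse leaf's corner nodes at its position.
hanging_constraints <- function(mesh) {
  cons <- list()
  ne <- nrow(mesh$elems)
  node_elem_count <- tabulate(as.vector(mesh$elems), nbins = nrow(mesh$nodes))
  for (n in seq_len(nrow(mesh$nodes))) {
    p <- mesh$nodes[n, ]
    # probe the eight octants around the node for containing leaves
    for (sx in c(-1, 1)) for (sy in c(-1, 1)) for (sz in c(-1, 1)) {
      q <- p + c(sx, sy, sz) * min(mesh$elem_size) / 4
      r <- octree_locate(mesh$leaves, mesh$subdivided, mesh$grid$origin,
                         mesh$grid$h, q)
      if (is.null(r)) next
      corners <- mesh$elems[r, ]
      if (n %in% corners) next
      # p lies inside/on leaf r but is not a corner: hanging
      s <- mesh$elem_size[r]
      c0 <- mesh$nodes[corners[1], ]
      f <- (p - c0) / s
      w <- as.numeric(interp_weights("trilinear", f[1], f[2], f[3], s))
      keep <- w > 1e-12
      cons[[length(cons) + 1L]] <- list(node = n, masters = corners[keep],
                                        weights = w[keep])
      break
    }
    if (length(cons) && cons[[length(cons)]]$node == n) next
  }
  # deduplicate by node
  if (length(cons)) {
    nn <- vapply(cons, `[[`, integer(1), "node")
    cons <- cons[!duplicated(nn)]
  }
  cons
}

# ---- queries ---------------------------------------------------------------

#' Locate the element containing a point
#'
#' @param mesh a [build_mesh()] result.
#' @param p world point (mm), length 3.
#' @return `NULL` when `p` is outside the mesh; otherwise a list with
#'   `element` (id) and `local` (trilinear coordinates in `[-1, 1]^3` that
#'   reproduce `p` under the element's trilinear map). Points on shared faces
#'   resolve to the lower element id.
#' @export
locate_element <- function(mesh, p) {
  p <- as.numeric(p)
  if (isTRUE(mesh$uniform)) {
    g <- mesh$grid
    t <- (p - g$origin) / g$h
    e <- floor(t)
    on_face <- t == e & e > 0
    e[on_face] <- e[on_face] - 1  # tie toward the lower element id
    if (any(e < 0) || any(e >= g$ndiv)) return(NULL)
    id <- (e[1] + 1) + e[2] * g$ndiv[1] + e[3] * g$ndiv[1] * g$ndiv[2]
    local <- 2 * (t - e) - 1
    return(list(element = as.integer(id), local = local))
  }
  r <- octree_locate(mesh$leaves, mesh$subdivided, mesh$grid$origin,
                     mesh$grid$h, p)
  if (is.null(r)) {
    # retry with a nudge for points exactly on faces
    r <- octree_locate(mesh$leaves, mesh$subdivided, mesh$grid$origin,
                       mesh$grid$h, p - min(mesh$elem_size) * 1e-7)
    if (is.null(r)) return(NULL)
  }
  c0 <- mesh$nodes[mesh$elems[r, 1], ]
  local <- 2 * (p - c0) / mesh$elem_size[r] - 1
  if (any(local < -1 - 1e-9) || any(local > 1 + 1e-9)) return(NULL)
  list(element = as.integer(r), local = pmin(pmax(local, -1), 1))
}

#' Surface nodes of an organ with outward normals
#'
#' Nodes on faces separating elements of the given label from
#' differently-labelled or exterior elements. Normals are the unit average of
#' incident boundary-face normals, oriented away from the organ.
#'
#' @param mesh a [build_mesh()] result.
#' @param label organ label value or name-free integer present in
#'   `mesh$elem_label`.
#' @return List with `nodes` (indices), `positions` (n x 3 mm) and `normals`
#'   (n x 3 unit vectors).
#' @export
surface_nodes <- function(mesh, label) {
  label <- as.integer(label)
  key <- paste0("surf_", label)
  if (!is.null(mesh$cache) && !is.null(mesh$cache[[key]]))
    return(mesh$cache[[key]])
  sel <- which(mesh$elem_label == label)
  if (!length(sel)) stop("label ", label, " absent from mesh")
  out <- boundary_faces_of(mesh, sel)
  if (!is.null(mesh$cache)) mesh$cache[[key]] <- out
  out
}

# Shared face-hash boundary extraction over an element subset.
boundary_faces_of <- function(mesh, sel) {
  # local corner indices of the 6 faces (VTK hex ordering), with outward axes
  faces_idx <- rbind(c(1, 4, 8, 5), c(2, 3, 7, 6),  # -x, +x
                     c(1, 2, 6, 5), c(4, 3, 7, 8),  # -y, +y
                     c(1, 2, 3, 4), c(5, 6, 7, 8))  # -z, +z
  face_dir <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0),
                    c(0, 0, -1), c(0, 0, 1))
  el <- mesh$elems[sel, , drop = FALSE]
  nfc <- 6L * nrow(el)
  fnodes <- matrix(0L, nfc, 4L)
  fdir <- matrix(0, nfc, 3)
  for (f in 1:6) {
    rows <- seq_len(nrow(el)) + (f - 1L) * nrow(el)
    fnodes[rows, ] <- el[, faces_idx[f, ], drop = FALSE]
    fdir[rows, ] <- matrix(face_dir[f, ], nrow(el), 3, byrow = TRUE)
  }
  # sort the 4 node ids per face with a sorting network (vectorised)
  a <- fnodes[, 1]; b <- fnodes[, 2]; cc_ <- fnodes[, 3]; d <- fnodes[, 4]
  s1 <- pmin(a, b); s2 <- pmax(a, b); s3 <- pmin(cc_, d); s4 <- pmax(cc_, d)
  lo <- pmin(s1, s3); hi <- pmax(s2, s4)
  m1 <- pmax(s1, s3); m2 <- pmin(s2, s4)
  skey <- paste(lo, pmin(m1, m2), pmax(m1, m2), hi, sep = "_")
  once <- !(skey %in% skey[duplicated(skey)])
  bn <- fnodes[once, , drop = FALSE]
  bd <- fdir[once, , drop = FALSE]
  ids <- sort(unique(as.vector(bn)))
  normals <- matrix(0, length(ids), 3)
  row <- match(as.vector(bn), ids)
  for (cc in 1:3) {
    acc <- rowsum(rep(bd[, cc], times = 4), row)
    normals[as.integer(rownames(acc)), cc] <-
      normals[as.integer(rownames(acc)), cc] + acc
  }
  nrm <- sqrt(rowSums(normals^2))
  nrm[nrm == 0] <- 1
  list(nodes = ids, positions = mesh$nodes[ids, , drop = FALSE],
       normals = normals / nrm)
}

# Nodes of the far-field Dirichlet set. `far_field = "all"` fixes the whole
# outer box; `"zfaces"` fixes only the inferior and superior faces (tissue
# continuation along the body axis), leaving the lateral faces traction-free.
mesh_boundary_nodes <- function(mesh, far_field = "all") {
  key <- paste0("outer_", far_field)
  if (!is.null(mesh$cache) && !is.null(mesh$cache[[key]]))
    return(mesh$cache[[key]])
  if (isTRUE(mesh$uniform)) {
    # structured grid: boundary lattice nodes directly
    nd <- mesh$grid$ndiv + 1L
    i <- rep(seq_len(nd[1]), times = nd[2] * nd[3])
    j <- rep(rep(seq_len(nd[2]), each = nd[1]), times = nd[3])
    k <- rep(seq_len(nd[3]), each = nd[1] * nd[2])
    out <- if (far_field == "zfaces") {
      which(k == 1L | k == nd[3])
    } else {
      which(i == 1L | i == nd[1] | j == 1L | j == nd[2] |
              k == 1L | k == nd[3])
    }
  } else {
    out <- boundary_faces_of(mesh, seq_len(nrow(mesh$elems)))$nodes
    if (far_field == "zfaces") {
      zr <- range(mesh$nodes[, 3])
      out <- out[mesh$nodes[out, 3] < zr[1] + 1e-9 |
                   mesh$nodes[out, 3] > zr[2] - 1e-9]
    }
  }
  if (!is.null(mesh$cache)) mesh$cache[[key]] <- out
  out
}

#' Export a mesh as a legacy-ASCII VTK unstructured grid
#'
#' Hexahedron cells (VTK type 12) with the organ label as cell data, for
#' inspection in standard mesh viewers.
#'
#' @param mesh a [build_mesh()] result.
#' @param path output `.vtk` path.
#' @export
write_mesh_vtk <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "hexahedral organ mesh",
               "ASCII", "DATASET UNSTRUCTURED_GRID",
               paste("POINTS", nrow(mesh$nodes), "double")), con)
  write(t(mesh$nodes), con, ncolumns = 3)
  ne <- nrow(mesh$elems)
  writeLines(paste("CELLS", ne, ne * 9), con)
  write(t(cbind(8L, mesh$elems - 1L)), con, ncolumns = 9)
  writeLines(paste("CELL_TYPES", ne), con)
  write(rep(12L, ne), con, ncolumns = 1)
  writeLines(c(paste("CELL_DATA", ne), "SCALARS organ_label int 1",
               "LOOKUP_TABLE default"), con)
  write(mesh$elem_label, con, ncolumns = 1)
  invisible(path)
}
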