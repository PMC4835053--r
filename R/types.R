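#' @useDynLib femablate, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom methods as
#' @importFrom stats rnorm runif median setNames
#' @importFrom utils write.csv
NULL

# Default organ label dictionary used throughout the package.
default_label_dictionary <- function() {
  c(background = 0L, prostate = 1L, bladder = 2L, rectum = 3L, ablation_zone = 4L)
}

#' 3D scalar volume with geometry metadata
#'
#' A minimal container for a 3D image: a numeric array plus voxel spacing and
#' the world position (mm) of the centre of voxel `[1, 1, 1]`. The direction
#' matrix is assumed to be the identity: a voxel with 1-based index
#' `(i, j, k)` sits at `origin + (c(i, j, k) - 1) * spacing`. Oblique
#' acquisitions must be resampled upstream.
#'
#' @param data numeric 3D array of intensities.
#' @param spacing numeric length-3, voxel spacing in mm (all > 0).
#' @param origin numeric length-3, world position (mm) of the first voxel
#'   centre.
#' @return An object of class `vol3d`.
#' @export
vol3d <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("'data' must be a 3D array, got ", length(dim(data)), " dimension(s)")
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be three positive finite numbers")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("'origin' must be three finite numbers")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "vol3d")
}

#' Multi-label segmentation volume
#'
#' A [vol3d()] whose voxels are integer organ labels, together with a label
#' dictionary mapping label values to organ names (0 is always background).
#'
#' @param data integer 3D array of labels.
#' @param spacing,origin as in [vol3d()].
#' @param dictionary named integer vector mapping organ name to label value;
#'   every nonzero label present in `data` must appear in it.
#' @return An object of class `c("labelmap", "vol3d")`.
#' @export
labelmap <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                     dictionary = default_label_dictionary()) {
  v <- vol3d(data, spacing, origin)
  storage.mode(v$data) <- "integer"
  present <- sort(unique(as.integer(v$data)))
  unknown <- setdiff(present[present != 0L], as.integer(dictionary))
  if (length(unknown))
    stop("label map contains labels absent from the dictionary: ",
         paste(unknown, collapse = ", "))
  if (all(present == 0L))
    warning("label map is empty (all background)")
  v$dictionary <- dictionary
  class(v) <- c("labelmap", "vol3d")
  v
}

#' Dense voxel-wise displacement field
#'
#' Per-voxel 3-vector displacements in world mm on a regular grid. A field `d`
#' realises the transformation `T(c) = c + d(c)` used in backward warping:
#' the warped image at voxel centre `c` samples the input at `c + d(c)`.
#'
#' @param data numeric 4D array, `dim = c(nx, ny, nz, 3)`, mm.
#' @param spacing,origin grid geometry as in [vol3d()].
#' @return An object of class `dispfield`.
#' @export
dispfield <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 4L || dim(data)[4] != 3L)
    stop("'data' must be a 4D array with 3 components in the 4th dimension")
  if (any(!is.finite(data))) stop("displacement field contains non-finite components")
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(spacing <= 0)) stop("'spacing' must be positive")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "dispfield")
}

#' @export
print.vol3d <- function(x, ...) {
  cat("<vol3d> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm, origin (", paste(signif(x$origin, 4), collapse = ", "), ") mm\n",
      sep = "")
  cat("  intensity range [", signif(min(x$data), 4), ", ",
      signif(max(x$data), 4), "]\n", sep = "")
  invisible(x)
}

#' @export
print.labelmap <- function(x, ...) {
  cat("<labelmap> ", paste(dim(x$data), collapse = " x "), " voxels, spacing ",
      paste(signif(x$spacing, 4), collapse = " x "), " mm\n", sep = "")
  tab <- table(factor(x$data, levels = as.integer(x$dictionary),
                      labels = names(x$dictionary)))
  tab <- tab[tab > 0]
  cat("  voxels per organ: ",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
print.dispfield <- function(x, ...) {
  m <- sqrt(x$data[, , , 1]^2 + x$data[, , , 2]^2 + x$data[, , , 3]^2)
  cat("<dispfield> ", paste(dim(x$data)[1:3], collapse = " x "),
      " voxels, max |d| = ", signif(max(m), 4), " mm\n", sep = "")
  invisible(x)
}

# ---- geometry helpers (internal) ------------------------------------------

grid_dims <- function(x) dim(x$data)[1:3]

# World coordinates (mm) of all voxel centres, as an n x 3 matrix in
# column-major voxel order (matching as.vector of the data array).
voxel_centers <- function(x) {
  d <- grid_dims(x)
  i <- seq_len(d[1]); j <- seq_len(d[2]); k <- seq_len(d[3])
  cbind(
    rep(x$origin[1] + (i - 1) * x$spacing[1], times = d[2] * d[3]),
    rep(rep(x$origin[2] + (j - 1) * x$spacing[2], each = d[1]), times = d[3]),
    rep(x$origin[3] + (k - 1) * x$spacing[3], each = d[1] * d[2])
  )
}

# Continuous 1-based voxel index of world points (n x 3 matrix).
world_to_index <- function(x, p) {
  cbind((p[, 1] - x$origin[1]) / x$spacing[1] + 1,
        (p[, 2] - x$origin[2]) / x$spacing[2] + 1,
        (p[, 3] - x$origin[3]) / x$spacing[3] + 1)
}

same_grid <- function(a, b, tol = 1e-6) {
  all(grid_dims(a) == grid_dims(b)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

stop_grid_mismatch <- function(a, b, what = "inputs") {
  if (!all(grid_dims(a) == grid_dims(b)))
    stop(what, " differ in dims: ", paste(grid_dims(a), collapse = "x"),
         " vs ", paste(grid_dims(b), collapse = "x"))
  if (!all(abs(a$spacing - b$spacing) < 1e-6))
    stop(what, " differ in spacing")
  if (!all(abs(a$origin - b$origin) < 1e-6))
    stop(what, " differ in origin")
  invisible(TRUE)
}

# Binary mask (3D logical array) of one organ of a labelmap.
organ_mask <- function(labels, organ) {
  lab <- organ_label_value(labels, organ)
  labels$data == lab
}

organ_label_value <- function(labels, organ) {
  if (is.character(organ)) {
    if (!organ %in% names(labels$dictionary))
      stop("organ '", organ, "' not in label dictionary")
    unname(labels$dictionary[[organ]])
  } else as.integer(organ)
}

# Run code with a deterministic RNG state, restoring the caller's state.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}
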