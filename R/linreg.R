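# Mutual-information linear (translation + rotation + scaling) alignment.

#' 9-parameter linear transform
#'
#' Translation, ZYX Euler rotation and per-axis scaling about a fixed centre
#' (by convention the moving image's centroid). Maps moving-image world
#' coordinates to fixed-image world coordinates:
#' `p' = center + translation + Rz Ry Rx diag(scale) (p - center)`.
#'
#' @param translation mm triple.
#' @param rotation Euler angles in radians, applied in ZYX order.
#' @param scale per-axis factors, > 0.
#' @param center rotation/scaling centre, mm.
#' @return An object of class `linear_transform`.
#' @export
linear_transform <- function(translation = c(0, 0, 0), rotation = c(0, 0, 0),
                             scale = c(1, 1, 1), center = c(0, 0, 0)) {
  stopifnot(length(translation) == 3, length(rotation) == 3,
            length(scale) == 3, all(scale > 0), length(center) == 3)
  structure(list(translation = as.numeric(translation),
                 rotation = as.numeric(rotation),
                 scale = as.numeric(scale),
                 center = as.numeric(center)),
            class = "linear_transform")
}

#' @export
print.linear_transform <- function(x, ...) {
  cat("<linear_transform> t = (", paste(signif(x$translation, 4), collapse = ", "),
      ") mm, r = (", paste(signif(x$rotation, 4), collapse = ", "),
      ") rad, s = (", paste(signif(x$scale, 4), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

rotation_matrix_zyx <- function(r) {
  cx <- cos(r[1]); sx <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

#' Homogeneous matrix of a linear transform
#'
#' @param t a [linear_transform()].
#' @return 4 x 4 homogeneous matrix mapping moving to fixed coordinates.
#' @export
as_matrix <- function(t) {
  A <- rotation_matrix_zyx(t$rotation) %*% diag(t$scale)
  b <- t$center + t$translation - A %*% t$center
  rbind(cbind(A, as.numeric(b)), c(0, 0, 0, 1))
}

#' Recover transform parameters from a homogeneous matrix
#'
#' Decomposes the linear part as rotation times positive per-axis scaling
#' (the family [linear_transform()] spans; reflections are rejected), so
#' `as_matrix(linear_transform_from_matrix(M)) == M` up to floating error.
#'
#' @param M 4 x 4 homogeneous matrix.
#' @param center rotation/scaling centre of the result, mm.
#' @return A [linear_transform()].
#' @export
linear_transform_from_matrix <- function(M, center = c(0, 0, 0)) {
  stopifnot(is.matrix(M), all(dim(M) == c(4, 4)))
  A <- M[1:3, 1:3]
  s <- sqrt(colSums(A^2))
  if (any(s <= 0) || det(A) <= 0)
    stop("matrix is singular or contains a reflection")
  R <- A %*% diag(1 / s)
  ry <- asin(max(-1, min(1, -R[3, 1])))
  rx <- atan2(R[3, 2], R[3, 3])
  rz <- atan2(R[2, 1], R[1, 1])
  b <- M[1:3, 4]
  translation <- b - center + as.numeric(A %*% center)
  linear_transform(translation = translation, rotation = c(rx, ry, rz),
                   scale = s, center = center)
}

#' Invert a linear transform
#'
#' @param t a [linear_transform()].
#' @return The [linear_transform()] mapping fixed back to moving
#'   coordinates, about the same centre.
#' @export
invert_linear <- function(t) {
  linear_transform_from_matrix(solve(as_matrix(t)), center = t$center)
}

#' Mutual information between two volumes on a shared grid
#'
#' Histogram estimator in nats: intensities are linearly binned over each
#' image's range on the evaluation domain and
#' `MI = sum p(x, y) log(p(x, y) / (p(x) p(y)))`.
#'
#' @param a,b [vol3d()] volumes on the same grid.
#' @param bins number of histogram bins per image.
#' @return MI in nats (non-negative up to floating error). A constant image
#'   yields 0 with a warning.
#' @export
mutual_information <- function(a, b, bins = 32) {
  stop_grid_mismatch(a, b, "images")
  mi_pair(as.numeric(a$data), as.numeric(b$data), bins)
}

mi_pair <- function(va, vb, bins) {
  ok <- is.finite(va) & is.finite(vb)
  va <- va[ok]; vb <- vb[ok]
  if (!length(va)) stop("no overlapping samples for mutual information")
  ra <- range(va); rb <- range(vb)
  if (ra[1] == ra[2] || rb[1] == rb[2]) {
    warning("constant image: mutual information is degenerate (0)")
    return(0)
  }
  ia <- pmin(floor((va - ra[1]) / (ra[2] - ra[1]) * bins) + 1L, bins)
  ib <- pmin(floor((vb - rb[1]) / (rb[2] - rb[1]) * bins) + 1L, bins)
  joint <- tabulate(ia + bins * (ib - 1L), nbins = bins * bins)
  n <- length(va)
  pj <- joint / n
  pa <- rowSums(matrix(pj, bins, bins))
  pb <- colSums(matrix(pj, bins, bins))
  nz <- pj > 0
  outer_p <- as.numeric(outer(pa, pb))
  sum(pj[nz] * log(pj[nz] / outer_p[nz]))
}

#' Resample a volume under a linear transform
#'
#' Backward resampling: the output voxel at fixed-grid position `c` samples
#' the moving image at `T^{-1}(c)`. Label maps use nearest-neighbour.
#'
#' @param img moving [vol3d()] or [labelmap()].
#' @param t a [linear_transform()] mapping moving to fixed coordinates.
#' @param grid object carrying the output grid geometry (default: `img`).
#' @param interp `"linear"` or `"nearest"`.
#' @param fill value for samples outside the moving image.
#' @return Resampled object of the same class as `img`.
#' @export
apply_linear <- function(img, t, grid = NULL, interp = c("linear", "nearest"),
                         fill = 0) {
  interp <- match.arg(interp)
  if (inherits(img, "labelmap")) interp <- "nearest"
  if (is.null(grid)) grid <- img
  Minv <- solve(as_matrix(t))
  p <- voxel_centers(grid)
  q <- cbind(p, 1) %*% t(Minv)
  vals <- sample_volume(img, q[, 1:3, drop = FALSE], interp = interp,
                        fill = fill)
  d <- grid_dims(grid)
  if (inherits(img, "labelmap")) {
    labelmap(array(as.integer(vals), dim = d), grid$spacing, grid$origin,
             img$dictionary)
  } else {
    vol3d(array(vals, dim = d), grid$spacing, grid$origin)
  }
}

#' Mutual-information linear registration
#'
#' Regular-step gradient ascent on the mutual information between the fixed
#' image and the linearly resampled moving image, over 9 parameters
#' (translation, ZYX rotation, per-axis scale) with a multiresolution
#' pyramid. Parameters are scaled so one step unit moves the image boundary
#' by roughly 1 mm. Deterministic given inputs and options.
#'
#' @param moving,fixed [vol3d()] volumes.
#' @param opts list: `bins` (32), `levels` (3), `max_iter` per level (50),
#'   `min_step` (0.02 mm), `pyramid` (TRUE; FALSE registers at full
#'   resolution only).
#' @return A [linear_transform()] mapping moving to fixed coordinates, with
#'   attribute `telemetry` (accepted-objective trace per level).
#' @export
register_linear <- function(moving, fixed, opts = list()) {
  o <- modifyList(list(bins = 32, levels = 3, max_iter = 50, min_step = 0.02,
                       pyramid = TRUE), opts)
  center <- moving$origin + (grid_dims(moving) - 1) * moving$spacing / 2
  r_eff <- mean((grid_dims(fixed) - 1) * fixed$spacing) / 2
  if (r_eff <= 0) stop("degenerate fixed image")
  # parameter vector u: translation mm, rotation*r_eff, (scale-1)*r_eff
  to_transform <- function(u) {
    linear_transform(translation = u[1:3], rotation = u[4:6] / r_eff,
                     scale = 1 + u[7:9] / r_eff, center = center)
  }
  nlev <- if (o$pyramid) o$levels else 1
  pyr_f <- list(fixed); pyr_m <- list(moving)
  for (l in seq_len(nlev - 1)) {
    pyr_f[[l + 1]] <- downsample_mean(pyr_f[[l]])
    pyr_m[[l + 1]] <- downsample_mean(pyr_m[[l]])
  }
  u <- numeric(9)
  telemetry <- list()
  for (lev in rev(seq_len(nlev))) {
    fx <- pyr_f[[lev]]; mv <- pyr_m[[lev]]
    objective <- function(uu) {
      t <- to_transform(uu)
      w <- apply_linear(mv, t, grid = fx, fill = NA)
      vals <- mi_overlap(as.numeric(w$data), as.numeric(fx$data), o$bins)
      vals
    }
    step <- 2 * mean(fx$spacing)
    delta <- 0.5 * mean(fx$spacing)
    f0 <- objective(u)
    trace <- f0
    for (it in seq_len(o$max_iter)) {
      g <- vapply(1:9, function(kk) {
        e <- numeric(9); e[kk] <- delta
        (objective(u + e) - objective(u - e)) / (2 * delta)
      }, numeric(1))
      gn <- sqrt(sum(g^2))
      if (gn < 1e-12) break
      cand <- u + step * g / gn
      fc <- objective(cand)
      if (fc > f0) {
        u <- cand; f0 <- fc
        trace <- c(trace, fc)
      } else {
        step <- step / 2
      }
      if (step < o$min_step) break
    }
    telemetry[[paste0("level", lev)]] <- trace
  }
  out <- to_transform(u)
  attr(out, "telemetry") <- telemetry
  out
}

# MI restricted to the overlap (NA marks out-of-moving samples); silent on
# degenerate histograms (returns 0) so optimizer probes never warn.
mi_overlap <- function(va, vb, bins) {
  ok <- is.finite(va) & is.finite(vb)
  if (sum(ok) < 32) return(-Inf)
  va <- va[ok]; vb <- vb[ok]
  ra <- range(va); rb <- range(vb)
  if (ra[1] == ra[2] || rb[1] == rb[2]) return(0)
  ia <- pmin(floor((va - ra[1]) / (ra[2] - ra[1]) * bins) + 1L, bins)
  ib <- pmin(floor((vb - rb[1]) / (rb[2] - rb[1]) * bins) + 1L, bins)
  joint <- tabulate(ia + bins * (ib - 1L), nbins = bins * bins)
  pj <- joint / length(va)
  pa <- rowSums(matrix(pj, bins, bins))
  pb <- colSums(matrix(pj, bins, bins))
  nz <- pj > 0
  outer_p <- as.numeric(outer(pa, pb))
  sum(pj[nz] * log(pj[nz] / outer_p[nz]))
}

# 2x mean-pooled downsampling (acts as smoothing + decimation for the
# registration pyramid).
downsample_mean <- function(img) {
  d <- grid_dims(img)
  d2 <- pmax(1L, d %/% 2L)
  s <- function(o1, o2, o3) {
    img$data[seq(o1, by = 2, length.out = d2[1]),
             seq(o2, by = 2, length.out = d2[2]),
             seq(o3, by = 2, length.out = d2[3]), drop = FALSE]
  }
  pooled <- (s(1, 1, 1) + s(2, 1, 1) + s(1, 2, 1) + s(2, 2, 1) +
               s(1, 1, 2) + s(2, 1, 2) + s(1, 2, 2) + s(2, 2, 2)) / 8
  vol3d(array(pooled, d2), img$spacing * 2, img$origin + img$spacing / 2)
}
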