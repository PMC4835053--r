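# Three-stage decomposition of post-treatment change:
#   stage 1: linear alignment (patient positioning),
#   stage 2: organ-driven deformation removal (bladder/rectum FEM),
#   stage 3: residual treatment deformation (prostate FEM).

#' Pipeline configuration
#'
#' All tunable parameters of the registration pipeline with their defaults.
#' Unknown arguments are rejected.
#'
#' @param working_spacing isotropic working-grid spacing, mm.
#' @param hex_size FEM element edge length, mm. 1 mm is the model's
#'   operating point; 3 mm is the desk-scale default used by the packaged
#'   experiments.
#' @param margin background-element margin around the organs, mm.
#' @param material a [material_params()].
#' @param solver_tol,solver_max_iter,solver_method BiCGStab controls.
#' @param load_mode `"prescribed_displacement"` (tolerance-free default) or
#'   `"force"` (spring-scaled forces; reproduces the Young's-modulus
#'   sensitivity of the organ-deformation removal).
#' @param gating correspondence gating radius, mm.
#' @param spring_reference_kpa reference modulus embedded in the force-mode
#'   spring constant (the soft-tissue assumption); held fixed during modulus
#'   sweeps.
#' @param force_iters,force_tol,force_clamp force-mode iteration cap,
#'   surface-residual convergence threshold (mm RMS), and per-iteration step
#'   clamp (multiple of the residual RMS).
#' @param organ_outer_iters outer iterations of the organ-deformation
#'   removal: after each solve the model is rebuilt on the corrected
#'   configuration and the residual matching is solved again (the
#'   per-iteration fields are composed).
#' @param t3_iters correspondence refinements for the prostate FEM.
#' @param mi_bins,mi_levels,mi_max_iter mutual-information registration
#'   controls.
#' @param far_field far-field fixation: `"all"` clamps the whole outer mesh
#'   box, `"zfaces"` clamps only the inferior/superior faces (tissue
#'   continuation along the body axis) and leaves the lateral faces free.
#' @param do_linear run the linear stage (disable when inputs are already
#'   aligned).
#' @param interp_scheme nodal-displacement interpolation scheme, see
#'   [interpolate_displacements()].
#' @param seed seed recorded in provenance (the pipeline itself is
#'   deterministic).
#' @return An object of class `fem_control`.
#' @export
fem_control <- function(working_spacing = 1, hex_size = 3, margin = 9,
                        material = material_params(), solver_tol = 1e-6,
                        solver_max_iter = 4000, solver_method = "bicgstab",
                        load_mode = c("prescribed_displacement", "force"),
                        gating = 20, spring_reference_kpa = 30,
                        force_iters = 12, force_tol = 0.1, force_clamp = 2,
                        organ_outer_iters = 2, t3_iters = 2,
                        mi_bins = 32, mi_levels = 3,
                        mi_max_iter = 50, far_field = c("zfaces", "all"),
                        do_linear = TRUE,
                        interp_scheme = "trilinear", seed = 1L, ...) {
  extra <- list(...)
  if (length(extra))
    stop("unknown configuration key(s): ", paste(names(extra), collapse = ", "))
  stopifnot(inherits(material, "material_params"), working_spacing > 0,
            hex_size > 0, gating > 0, force_iters >= 1, force_clamp > 0)
  structure(list(working_spacing = working_spacing, hex_size = hex_size,
                 margin = margin, material = material,
                 solver_tol = solver_tol, solver_max_iter = solver_max_iter,
                 solver_method = solver_method,
                 load_mode = match.arg(load_mode), gating = gating,
                 spring_reference_kpa = spring_reference_kpa,
                 force_iters = force_iters, force_tol = force_tol,
                 force_clamp = force_clamp,
                 organ_outer_iters = organ_outer_iters, t3_iters = t3_iters,
                 mi_bins = mi_bins, mi_levels = mi_levels,
                 mi_max_iter = mi_max_iter,
                 far_field = match.arg(far_field), do_linear = do_linear,
                 interp_scheme = interp_scheme, seed = as.integer(seed)),
            class = "fem_control")
}

#' Remove bladder/rectum-driven deformation (stage 2)
#'
#' Builds the FEM on the (linearly aligned) post-treatment configuration and
#' drives its bladder and rectum surfaces toward their pre-treatment
#' counterparts; because the solve direction is post-to-pre, the result
#' directly realises the inverse organ deformation — no numeric field
#' inversion is involved. The prostate receives no direct load and moves
#' only through elastic transmission.
#'
#' In `force` mode the surface displacements become spring-scaled nodal
#' forces applied in a safeguarded iteration: the spring constant is
#' calibrated once against the reference soft-tissue modulus
#' (`spring_reference_kpa`), so solving with a stiffer or softer material
#' under- or over-corrects — the mechanism probed by the Young's-modulus
#' sweep. Each iteration's step is clamped to `force_clamp` times the
#' current surface residual and the iterate with the smallest residual is
#' kept.
#'
#' @param pre_labels pre-treatment [labelmap()] (target configuration).
#' @param post_labels,post_image linearly aligned post-treatment label map
#'   and image on the same grid.
#' @param material a [material_params()] used for the solve.
#' @param control a [fem_control()].
#' @param fem optional precomputed list `(mesh, K1)` for the post
#'   configuration (`K1` assembled at unit Young's modulus).
#' @return List: `field` (the correction [dispfield()]), corrected `image`
#'   and `labels`, and `telemetry` (iterations, surface residuals, solver
#'   iterations).
#' @export
remove_organ_deformation <- function(pre_labels, post_labels, post_image,
                                     material = material_params(),
                                     control = fem_control(), fem = NULL) {
  dict <- pre_labels$dictionary
  for (org in c("bladder", "rectum")) {
    for (lm in list(pre_labels, post_labels))
      if (!any(lm$data == dict[[org]]))
        stop("stage 2 requires a ", org, " label in both label maps")
  }
  stop_grid_mismatch(pre_labels, post_labels, "label maps")
  # Outer iterations: solve the surface-matching FEM, warp, rebuild the
  # model on the corrected configuration and solve the residual matching.
  # This removes the second-order error of solving on the still-deformed
  # post geometry; the per-iteration fields are composed into one warp.
  cur_labels <- post_labels
  fields <- list()
  telem <- list()
  total <- NULL
  for (k in seq_len(max(1L, control$organ_outer_iters))) {
    if (k == 1L && !is.null(fem)) {
      mesh <- fem$mesh
      K1 <- fem$K1
    } else {
      mesh <- build_mesh(cur_labels, control$hex_size, control$hex_size,
                         margin = control$margin)
      K1 <- assemble_stiffness(mesh,
                               material_params(1, material$poisson_ratio))
    }
    drive <- drive_surfaces(mesh, c("bladder", "rectum"), cur_labels,
                            pre_labels, material, control, K1)
    fields[[k]] <- interpolate_displacements(mesh, -drive$U, post_labels,
                                             scheme = control$interp_scheme)
    telem[[k]] <- drive$telemetry
    total <- compose_fields(fields)
    cur_labels <- warp_image(post_labels, total)
    last_rms <- utils::tail(drive$telemetry$residual_rms, 1)
    if (length(last_rms) && last_rms < control$force_tol) break
  }
  list(field = total,
       image = warp_image(post_image, total, interp = "linear"),
       labels = cur_labels,
       telemetry = list(outer = telem,
                        residual_rms = utils::tail(telem, 1)[[1]]$residual_rms))
}

# Shared surface-driving solver. The organ surfaces are represented by
# their boundary-voxel clouds (image resolution); closest-point
# correspondences computed on the clouds are averaged onto the nearest
# organ-surface mesh nodes, which avoids the staircase bias of the
# element-resolution mesh boundary. Returns nodal displacement U (N x 3).
drive_surfaces <- function(mesh, organs, moving_labels, target_labels,
                           material, control, K1) {
  dict <- moving_labels$dictionary
  sets <- lapply(organs, function(org) {
    cloud <- surface_voxel_cloud(moving_labels, org)
    target <- surface_voxel_cloud(target_labels, org)
    if (!nrow(target)) stop("empty target surface for ", org)
    surf <- surface_nodes(mesh, dict[[org]])
    assign <- .cpp_nearest_index(cloud, surf$positions)
    list(cloud = cloud, target = target, nodes = surf$nodes, assign = assign)
  })
  drive_surface_sets(mesh, sets, material, control, K1)
}

# Core surface-driving iteration over prepared sets (each: moving cloud,
# target cloud, organ-surface mesh nodes, cloud-to-node assignment).
drive_surface_sets <- function(mesh, sets, material, control, K1) {
  n <- nrow(mesh$nodes)
  h <- control$hex_size
  corr <- function(U) {
    nodes <- integer(); disp <- NULL; sq <- 0; m <- 0L
    for (s in sets) {
      cur <- s$cloud + interp_nodal_at(mesh, U, s$cloud)
      d <- closest_point_displacement(cur, s$target, control$gating)
      keep <- !is.na(d[, 1])
      sq <- sq + sum(d[keep, ]^2); m <- m + sum(keep)
      dm <- rowsum(d[keep, , drop = FALSE], s$assign[keep])
      cnt <- as.numeric(table(s$assign[keep]))
      hit <- as.integer(rownames(dm))
      nodes <- c(nodes, s$nodes[hit])
      disp <- rbind(disp, dm / cnt)
    }
    if (!m) stop("all surface correspondences were gated out")
    list(nodes = nodes, disp = disp, rms = sqrt(sq / m))
  }
  if (control$load_mode == "prescribed_displacement") {
    KE <- K1 * material$youngs_modulus
    U <- matrix(0, n, 3)
    resids <- numeric(); its <- integer()
    for (it in seq_len(max(1L, control$t3_iters))) {
      cc <- corr(U)
      rms <- cc$rms
      resids <- c(resids, rms)
      if (rms < control$force_tol && it > 1) break
      total <- U[cc$nodes, , drop = FALSE] + cc$disp
      u <- solve_fem(mesh, material, dirichlet_nodes = cc$nodes,
                     dirichlet_disp = total, K = KE, tol = control$solver_tol,
                     max_iter = control$solver_max_iter,
                     method = control$solver_method,
                     far_field = control$far_field)
      its <- c(its, attr(u, "iterations"))
      U <- matrix(u, ncol = 3, byrow = TRUE)
    }
    return(list(U = U, telemetry = list(mode = "prescribed_displacement",
                                        residual_rms = resids,
                                        solver_iterations = its)))
  }
  # Force mode: safeguarded spring iteration. Correspondence displacements
  # become nodal forces; the force magnitude is set by a least-squares fit
  # of the *reference-modulus* response to the demanded displacements (the
  # soft-tissue assumption), so solving with a stiffer or softer material
  # under- or over-corrects by E_ref / E.
  E_ref <- control$spring_reference_kpa
  E <- material$youngs_modulus
  U <- matrix(0, n, 3)
  best <- list(U = U, rms = Inf)
  vprev <- NULL
  resids <- numeric(); its <- integer(); gammas <- numeric()
  for (it in seq_len(control$force_iters)) {
    cc <- corr(U)
    rms <- cc$rms
    resids <- c(resids, rms)
    if (rms < best$rms) best <- list(U = U, rms = rms)
    if (rms < control$force_tol) break
    F <- numeric(3 * n)
    dof <- 3 * (cc$nodes - 1)
    F[dof + 1] <- h * cc$disp[, 1]
    F[dof + 2] <- h * cc$disp[, 2]
    F[dof + 3] <- h * cc$disp[, 3]
    v <- solve_fem(mesh, material_params(1, material$poisson_ratio),
                   forces = F, K = K1, tol = control$solver_tol,
                   max_iter = control$solver_max_iter,
                   method = control$solver_method, x0 = vprev,
                   far_field = control$far_field)
    its <- c(its, attr(v, "iterations"))
    vprev <- v
    Vn <- matrix(v, ncol = 3, byrow = TRUE)
    # reference response (modulus E_ref) at the driven nodes
    rs <- Vn[cc$nodes, , drop = FALSE] / E_ref
    gamma <- sum(rs * cc$disp) / sum(rs * rs)
    if (!is.finite(gamma) || gamma <= 0)
      stop("spring calibration failed (projection ", signif(gamma, 3), ")")
    gammas <- c(gammas, gamma)
    inc <- gamma * Vn / E
    inc_rms <- sqrt(mean(rowSums(inc[cc$nodes, , drop = FALSE]^2)))
    cap <- control$force_clamp * rms
    if (inc_rms > cap) inc <- inc * cap / inc_rms
    U <- U + inc
  }
  cc <- corr(U)
  rms <- cc$rms
  resids <- c(resids, rms)
  if (rms < best$rms) best <- list(U = U, rms = rms)
  list(U = best$U,
       telemetry = list(mode = "force", residual_rms = resids,
                        best_residual_rms = best$rms,
                        solver_iterations = its, spring_gamma = gammas))
}

#' Estimate the treatment-induced deformation (stage 3)
#'
#' Builds the FEM on the pre-treatment configuration and drives the pre
#' prostate surface toward the corrected post-treatment prostate surface
#' (prescribed-displacement driving with correspondence refinement). The
#' returned field warps the pre image into alignment with the corrected
#' post image; its magnitude map is the treatment deformation heatmap.
#'
#' @param pre_image,pre_labels pre-treatment volume and labels.
#' @param post_image,post_labels stage-2-corrected post-treatment volume and
#'   labels on the same grid.
#' @inheritParams remove_organ_deformation
#' @return List: `field` (T3 as a [dispfield()]), `image`
#'   (the T3-warped pre image), `labels` (T3-warped pre labels),
#'   `telemetry`.
#' @export
estimate_treatment_deformation <- function(pre_image, pre_labels, post_image,
                                           post_labels,
                                           material = material_params(),
                                           control = fem_control(),
                                           fem = NULL) {
  dict <- pre_labels$dictionary
  for (lm in list(pre_labels, post_labels))
    if (!any(lm$data == dict[["prostate"]]))
      stop("stage 3 requires a prostate label in both label maps")
  stop_grid_mismatch(pre_labels, post_labels, "label maps")
  if (is.null(fem)) {
    mesh <- build_mesh(pre_labels, control$hex_size, control$hex_size,
                       margin = control$margin)
    K1 <- assemble_stiffness(mesh, material_params(1, material$poisson_ratio))
    fem <- list(mesh = mesh, K1 = K1)
  }
  ctl <- control
  ctl$load_mode <- "prescribed_displacement"
  drive <- drive_surfaces(fem$mesh, "prostate", pre_labels, post_labels,
                          material, ctl, fem$K1)
  field <- interpolate_displacements(fem$mesh, -drive$U, pre_labels,
                                     scheme = control$interp_scheme)
  list(field = field,
       image = warp_image(pre_image, field, interp = "linear"),
       labels = warp_image(pre_labels, field),
       telemetry = drive$telemetry)
}

#' Fit the three-stage biomechanical registration
#'
#' Runs linear alignment, organ-deformation removal, and treatment
#' deformation estimation on a pre/post MRI pair with matching label maps,
#' all on a common working grid.
#'
#' @param pre_image,pre_labels pre-treatment image and labels.
#' @param post_image,post_labels post-treatment image and labels.
#' @param control a [fem_control()].
#' @return An object of class `fem_registration` with components `t1`
#'   (the [linear_transform()]), `t2_field`, `t3_field`, aligned post and
#'   warped pre volumes/labels, per-stage telemetry and provenance.
#' @export
fem_register <- function(pre_image, pre_labels, post_image, post_labels,
                         control = fem_control()) {
  stopifnot(inherits(pre_image, "vol3d"), inherits(pre_labels, "labelmap"),
            inherits(post_image, "vol3d"), inherits(post_labels, "labelmap"))
  t_start <- Sys.time()
  ws <- control$working_spacing
  pre_image_w <- resample_iso(pre_image, ws)
  pre_labels_w <- resample_iso(pre_labels, ws)
  stage <- "linear alignment"
  res <- tryCatch({
    if (control$do_linear) {
      t1 <- register_linear(post_image, pre_image_w,
                            opts = list(bins = control$mi_bins,
                                        levels = control$mi_levels,
                                        max_iter = control$mi_max_iter))
      post_image_a <- apply_linear(post_image, t1, grid = pre_image_w)
      post_labels_a <- apply_linear(post_labels, t1, grid = pre_image_w)
    } else {
      t1 <- linear_transform()
      post_image_a <- resample_iso(post_image, ws)
      post_labels_a <- resample_iso(post_labels, ws)
      stop_grid_mismatch(pre_image_w, post_image_a, "pre/post working grids")
    }
    stage <- "organ-deformation removal"
    s2 <- remove_organ_deformation(pre_labels_w, post_labels_a, post_image_a,
                                   control$material, control)
    stage <- "treatment-deformation estimation"
    s3 <- estimate_treatment_deformation(pre_image_w, pre_labels_w,
                                         s2$image, s2$labels,
                                         control$material, control)
    list(t1 = t1, s2 = s2, s3 = s3,
         post_image_a = post_image_a, post_labels_a = post_labels_a)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  structure(list(
    t1 = res$t1,
    t2_field = res$s2$field,
    t3_field = res$s3$field,
    aligned_post_image = res$s2$image,
    aligned_post_labels = res$s2$labels,
    warped_pre_image = res$s3$image,
    warped_pre_labels = res$s3$labels,
    pre_image = pre_image_w,
    pre_labels = pre_labels_w,
    linear_post_image = res$post_image_a,
    linear_post_labels = res$post_labels_a,
    telemetry = list(stage2 = res$s2$telemetry, stage3 = res$s3$telemetry),
    provenance = list(control = control, seed = control$seed,
                      material = control$material,
                      started = format(t_start), finished = format(Sys.time()))
  ), class = "fem_registration")
}

#' @export
print.fem_registration <- function(x, ...) {
  cat("Biomechanical pre/post registration (3 stages)\n")
  cat("  working grid: ", paste(grid_dims(x$pre_image), collapse = " x "),
      " voxels at ", x$pre_image$spacing[1], " mm\n", sep = "")
  tp <- x$t1$translation
  cat("  stage 1 (linear): translation (",
      paste(signif(tp, 3), collapse = ", "), ") mm\n", sep = "")
  m2 <- max(magnitude_map(x$t2_field)$data)
  m3 <- max(magnitude_map(x$t3_field)$data)
  cat("  stage 2 (organ FEM): max correction ", signif(m2, 3), " mm\n",
      sep = "")
  cat("  stage 3 (treatment FEM): max deformation ", signif(m3, 3), " mm\n",
      sep = "")
  invisible(x)
}

#' @export
summary.fem_registration <- function(object, ...) {
  build_report(object)
}

#' @export
coef.fem_registration <- function(object, ...) {
  t1 <- object$t1
  c(setNames(t1$translation, c("tx", "ty", "tz")),
    setNames(t1$rotation, c("rx", "ry", "rz")),
    setNames(t1$scale, c("sx", "sy", "sz")))
}

#' @export
residuals.fem_registration <- function(object, ...) {
  list(stage2_surface_rms_mm = object$telemetry$stage2$residual_rms,
       stage3_surface_rms_mm = object$telemetry$stage3$residual_rms)
}

#' Apply fitted transforms to a new volume
#'
#' `from = "post"` maps a volume acquired in the post-treatment frame onto
#' the pre-treatment working grid (stage 1 then stage 2); `from = "pre"`
#' applies the treatment deformation (stage 3) to a pre-treatment volume.
#'
#' @param object a [fem_register()] fit.
#' @param newdata a [vol3d()] or [labelmap()].
#' @param from frame of `newdata`.
#' @param ... unused.
#' @export
predict.fem_registration <- function(object, newdata,
                                     from = c("post", "pre"), ...) {
  from <- match.arg(from)
  if (from == "post") {
    a <- apply_linear(newdata, object$t1, grid = object$pre_image)
    warp_image(a, object$t2_field,
               interp = if (inherits(newdata, "labelmap")) "nearest" else "linear")
  } else {
    warp_image(resample_iso(newdata, object$pre_image$spacing[1]),
               object$t3_field,
               interp = if (inherits(newdata, "labelmap")) "nearest" else "linear")
  }
}

#' Plot the treatment-deformation heatmap
#'
#' Axial slice of the stage-3 deformation magnitude (mm) with the prostate
#' outline.
#'
#' @param x a [fem_register()] fit.
#' @param slice axial slice index; default the prostate centroid slice.
#' @param ... passed to [graphics::image()].
#' @export
plot.fem_registration <- function(x, slice = NULL, ...) {
  mag <- magnitude_map(x$t3_field)
  pro <- organ_mask(x$pre_labels, "prostate")
  if (is.null(slice)) {
    zc <- which(pro, arr.ind = TRUE)[, 3]
    slice <- round(median(zc))
  }
  d <- grid_dims(mag)
  xs <- x$pre_image$origin[1] + (seq_len(d[1]) - 1) * x$pre_image$spacing[1]
  ys <- x$pre_image$origin[2] + (seq_len(d[2]) - 1) * x$pre_image$spacing[2]
  graphics::image(xs, ys, mag$data[, , slice],
                  col = grDevices::hcl.colors(64, "Reds", rev = TRUE),
                  xlab = "x (mm)", ylab = "y (mm)",
                  main = sprintf("treatment deformation |T3| (mm), slice %d",
                                 slice), ...)
  graphics::contour(xs, ys, pro[, , slice] * 1, levels = 0.5, add = TRUE,
                    drawlabels = FALSE, col = "blue")
  invisible(x)
}
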