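# Packaged experiments: the synthetic inversion-accuracy study (with its
# Young's-modulus sweep) and the end-to-end quantification chain.

#' Synthetic organ-deformation inversion experiment
#'
#' For each Young's modulus and each seeded force pattern: generate the
#' pelvic phantom, calibrate bladder/rectum surface forces so the prostate
#' Dice between the original and deformed phantom drops to `target_dice`,
#' apply the deformation, recover it with the organ-deformation-removal FEM
#' in force mode at the given modulus, and record the recovered prostate
#' Dice. The ground-truth deformation is always generated at the reference
#' soft-tissue modulus; only the recovery modulus is swept.
#'
#' @param youngs_sweep Young's moduli (kPa) to evaluate.
#' @param seeds seeds for the random force patterns (one repeat each).
#' @param target_dice starting prostate Dice after the synthetic
#'   deformation.
#' @param spec a [phantom_spec()]; the default is the desk-scale phantom
#'   (72 mm field of view at 1 mm).
#' @param control a [fem_control()]; `load_mode` is forced to `"force"`.
#' @param generation_material material used to generate the ground truth.
#' @param verbose print one line per run.
#' @return data.frame with columns `youngs_modulus`, `seed`, `force_scale`,
#'   `start_dice`, `recovered_dice`.
#' @export
experiment_e1 <- function(youngs_sweep = 30, seeds = 1:20,
                          target_dice = 0.65,
                          spec = phantom_spec(scale = 72 / 140),
                          control = fem_control(load_mode = "force"),
                          generation_material = material_params(),
                          verbose = FALSE) {
  stopifnot(all(youngs_sweep > 0))
  control$load_mode <- "force"
  phantom <- generate_phantom(spec)
  labels <- phantom$labels
  pre_mesh <- build_mesh(labels, control$hex_size, control$hex_size,
                         margin = control$margin)
  pre_K <- assemble_stiffness(pre_mesh, generation_material)
  gen_fem <- list(mesh = pre_mesh, K = pre_K)
  pro <- organ_mask(labels, "prostate")
  rows <- list()
  for (seed in seeds) {
    scale <- calibrate_force_scale(phantom, target_dice = target_dice,
                                   material = generation_material,
                                   seed = seed, hex_size = control$hex_size,
                                   margin = control$margin, fem = gen_fem)
    syn <- attr(scale, "deformation")
    field <- dispfield(syn$field$data * as.numeric(scale), labels$spacing,
                       labels$origin)
    post_labels <- warp_image(labels, field)
    post_image <- warp_image(phantom$image, field, interp = "linear")
    start_dice <- dice_coefficient(pro, organ_mask(post_labels, "prostate"))
    rec_mesh <- build_mesh(post_labels, control$hex_size, control$hex_size,
                           margin = control$margin)
    rec_K1 <- assemble_stiffness(rec_mesh,
                                 material_params(1, control$material$poisson_ratio))
    rec_fem <- list(mesh = rec_mesh, K1 = rec_K1)
    for (E in youngs_sweep) {
      mat <- material_params(E, control$material$poisson_ratio)
      rec <- remove_organ_deformation(labels, post_labels, post_image,
                                      material = mat, control = control,
                                      fem = rec_fem)
      d <- dice_coefficient(pro, organ_mask(rec$labels, "prostate"))
      rows[[length(rows) + 1L]] <-
        data.frame(youngs_modulus = E, seed = seed,
                   force_scale = as.numeric(scale),
                   start_dice = start_dice, recovered_dice = d)
      if (verbose)
        message(sprintf("E = %g kPa, seed %d: start %.3f -> recovered %.3f",
                        E, seed, start_dice, d))
    }
  }
  do.call(rbind, rows)
}

#' Plot a modulus sweep of the inversion experiment
#'
#' Recovered Dice against log10 Young's modulus (the sweep figure's axes).
#'
#' @param e1 result of [experiment_e1()].
#' @param ... passed to [graphics::plot()].
#' @export
plot_e1_sweep <- function(e1, ...) {
  agg <- stats::aggregate(recovered_dice ~ youngs_modulus, e1, mean)
  graphics::plot(log10(agg$youngs_modulus), agg$recovered_dice, type = "b",
                 xlab = "log10 Young's modulus (kPa)",
                 ylab = "recovered prostate Dice", ylim = c(0, 1), ...)
  graphics::abline(h = unique(e1$start_dice)[1], lty = 2, col = "grey50")
  invisible(agg)
}

#' End-to-end synthetic quantification experiment
#'
#' Builds the full synthetic pre/post chain — focal lesion, organ-driven
#' deformation, linear misalignment — runs the three-stage registration, and
#' compares the recovered quantities with the generated ground truth.
#'
#' @param spec a [phantom_spec()].
#' @param control a [fem_control()].
#' @param seed seed for the organ-deformation force pattern.
#' @param shrink_fraction target prostate volume decrease of the lesion.
#' @param intensity_delta lesion intensity change.
#' @param organ_dice starting prostate Dice induced by the organ
#'   deformation.
#' @param misalign [linear_transform()] applied to create the misaligned
#'   post image (NULL for a default small misalignment).
#' @return List: `result` (the [fem_register()] fit), `report`
#'   (the [build_report()] output), and `truth` (site, lesion field, applied
#'   transform, recovered-vs-true summaries).
#' @export
experiment_e2 <- function(spec = phantom_spec(scale = 72 / 140),
                          control = fem_control(), seed = 1L,
                          shrink_fraction = 0.05, intensity_delta = 25,
                          organ_dice = 0.75, misalign = NULL) {
  phantom <- generate_phantom(spec)
  labels <- phantom$labels
  # lesion site: off-centre inside the prostate, toward the rectum side
  pidx <- which(organ_mask(labels, "prostate"), arr.ind = TRUE)
  centroid <- labels$origin + (colMeans(pidx) - 1) * labels$spacing
  vpro <- organ_volume(labels, "prostate")
  r_eq <- (3 * vpro * 1000 / (4 * pi))^(1 / 3)
  site <- centroid + c(0.25, 0.35, 0) * r_eq
  lesioned <- embed_focal_lesion(phantom, site, shrink_fraction,
                                 intensity_delta,
                                 material = control$material,
                                 hex_size = control$hex_size,
                                 margin = control$margin)
  # organ-driven deformation applied on top of the lesioned anatomy
  lesphantom <- list(image = lesioned$image, labels = lesioned$labels)
  scale <- calibrate_force_scale(lesphantom, target_dice = organ_dice,
                                 material = control$material, seed = seed,
                                 hex_size = control$hex_size,
                                 margin = control$margin)
  syn <- attr(scale, "deformation")
  t2_true <- dispfield(syn$field$data * as.numeric(scale), labels$spacing,
                       labels$origin)
  post_image <- warp_image(lesioned$image, t2_true, interp = "linear")
  post_labels <- warp_image(lesioned$labels, t2_true)
  if (is.null(misalign)) {
    # patient repositioning between visits: rigid by default (same scanner
    # and calibrated field of view; scaling stays available in the linear
    # stage for acquisitions that need it)
    center <- labels$origin + (grid_dims(labels) - 1) * labels$spacing / 2
    misalign <- linear_transform(translation = c(4, -3, 2),
                                 rotation = c(0.03, -0.02, 0.04),
                                 center = center)
  }
  post_image_m <- apply_linear(post_image, misalign, grid = labels)
  post_labels_m <- apply_linear(post_labels, misalign, grid = labels)
  fit <- fem_register(phantom$image, labels, post_image_m, post_labels_m,
                      control = control)
  report <- build_report(fit)
  mag <- magnitude_map(fit$t3_field)
  imax <- which.max(mag$data)
  loc <- mag$origin + (as.numeric(arrayInd(imax, grid_dims(mag))) - 1) *
    mag$spacing
  truth <- list(
    site = site, lesion_field = lesioned$field, organ_field = t2_true,
    misalign = misalign,
    t3_peak_mm = loc,
    t3_peak_error_mm = sqrt(sum((loc - site)^2)),
    volume_change_true_percent = -100 * shrink_fraction,
    volume_change_recovered_percent =
      report$volume_change_percent[["prostate"]])
  list(result = fit, report = report, truth = truth)
}
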