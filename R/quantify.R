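# Outcome measures: Dice overlap, organ volumes and change, deformation
# heatmaps, relative intensity-difference maps, and the assembled report.

#' Dice similarity coefficient
#'
#' `2 |A intersect B| / (|A| + |B|)` between two binary masks on the same
#' grid. Two empty masks are defined to overlap perfectly (1, with a
#' warning).
#'
#' @param a,b logical 3D arrays, or [vol3d()]/[labelmap()] objects whose
#'   nonzero voxels form the masks (grids must then match).
#' @return Dice in `[0, 1]`.
#' @export
dice_coefficient <- function(a, b) {
  if (inherits(a, "vol3d") || inherits(b, "vol3d")) {
    stopifnot(inherits(a, "vol3d"), inherits(b, "vol3d"))
    stop_grid_mismatch(a, b, "masks")
    a <- a$data != 0
    b <- b$data != 0
  }
  if (!identical(dim(a), dim(b)))
    stop("masks differ in dims: ", paste(dim(a), collapse = "x"), " vs ",
         paste(dim(b), collapse = "x"))
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) {
    warning("both masks are empty; Dice defined as 1")
    return(1)
  }
  2 * sum(a & b) / (na + nb)
}

#' Organ volume in millilitres
#'
#' Voxel count times voxel volume. A missing organ yields 0 with a warning.
#'
#' @param labels a [labelmap()].
#' @param organ organ name or label value.
#' @return Volume in ml.
#' @export
organ_volume <- function(labels, organ) {
  lab <- organ_label_value(labels, organ)
  n <- sum(labels$data == lab)
  if (n == 0) warning("organ ", organ, " not present; volume 0")
  n * prod(labels$spacing) / 1000
}

#' Percent volume change
#'
#' `100 * (post - pre) / pre`. Note that for a cohort the change of the
#' medians and the median of per-case changes generally differ; this
#' function computes the per-case formula.
#'
#' @param pre_ml,post_ml volumes in ml; `pre_ml` must be positive.
#' @return Signed percent change.
#' @export
volume_change <- function(pre_ml, post_ml) {
  if (any(pre_ml <= 0)) stop("pre-treatment volume must be positive")
  100 * (post_ml - pre_ml) / pre_ml
}

#' Relative intensity-difference map
#'
#' Voxelwise `100 * |a - b| / reference` inside a mask, the map used to
#' localise post-ablation signal change. The default reference is the
#' masked mean of `a` (robust to near-zero voxels); `"per_voxel"` divides by
#' `max(|a|, eps)` voxelwise.
#'
#' @param a,b spatially aligned [vol3d()] volumes.
#' @param mask logical array (or mask-like [vol3d()]) of voxels to compare;
#'   must be non-empty.
#' @param reference `"masked_mean"` or `"per_voxel"`.
#' @param eps floor for the per-voxel reference.
#' @return A [vol3d()] of percent differences (zero outside the mask) with
#'   attributes `max_percent`, `mean_percent` and `argmax_mm`.
#' @export
intensity_difference_map <- function(a, b, mask,
                                     reference = c("masked_mean", "per_voxel"),
                                     eps = 1e-6) {
  reference <- match.arg(reference)
  stop_grid_mismatch(a, b, "images")
  if (inherits(mask, "vol3d")) mask <- mask$data != 0
  if (!identical(dim(mask), grid_dims(a))) stop("mask grid mismatch")
  if (!any(mask)) stop("empty mask")
  diffs <- abs(a$data - b$data)
  out <- array(0, grid_dims(a))
  ref <- if (reference == "masked_mean") {
    max(mean(abs(a$data[mask])), eps)
  } else {
    pmax(abs(a$data[mask]), eps)
  }
  out[mask] <- 100 * diffs[mask] / ref
  res <- vol3d(out, a$spacing, a$origin)
  imax <- which.max(out)
  loc <- arrayInd(imax, grid_dims(a))
  attr(res, "max_percent") <- max(out[mask])
  attr(res, "mean_percent") <- mean(out[mask])
  attr(res, "argmax_mm") <- a$origin + (as.numeric(loc) - 1) * a$spacing
  res
}

#' Assemble the quantification report
#'
#' Computes Dice per organ between the pre-treatment labels and the
#' organ-deformation-corrected post labels, the stage-3 surface-fit Dice,
#' organ volumes and percent change, the maximum treatment deformation and
#' its location, and intensity-difference statistics over the prostate.
#' Optionally serialises JSON + CSV and writes the heatmap volumes.
#'
#' @param result a [fem_register()] fit.
#' @param out_dir optional directory for `report.json`, `report.csv`,
#'   `t3_magnitude.nii.gz` and `intensity_diff.nii.gz`.
#' @return An object of class `quant_report`.
#' @export
build_report <- function(result, out_dir = NULL) {
  stopifnot(inherits(result, "fem_registration"))
  needed <- c("pre_labels", "aligned_post_labels", "warped_pre_image",
              "aligned_post_image", "t3_field")
  missing <- needed[vapply(needed, function(nm) is.null(result[[nm]]),
                           logical(1))]
  if (length(missing))
    stop("registration result lacks intermediates: ",
         paste(missing, collapse = ", "))
  pre <- result$pre_labels
  post <- result$aligned_post_labels
  organs <- intersect(names(pre$dictionary)[pre$dictionary > 0],
                      c("prostate", "bladder", "rectum"))
  dice_by_organ <- vapply(organs, function(org) {
    dice_coefficient(organ_mask(pre, org), organ_mask(post, org))
  }, numeric(1))
  fit_dice <- dice_coefficient(organ_mask(result$warped_pre_labels, "prostate"),
                               organ_mask(post, "prostate"))
  vols <- rbind(
    pre = vapply(organs, function(org) organ_volume(pre, org), numeric(1)),
    post = vapply(organs, function(org) organ_volume(post, org), numeric(1)))
  vchange <- volume_change(vols["pre", ], vols["post", ])
  mag <- magnitude_map(result$t3_field)
  imax <- which.max(mag$data)
  loc <- arrayInd(imax, grid_dims(mag))
  pro_mask <- organ_mask(pre, "prostate")
  idm <- intensity_difference_map(result$warped_pre_image,
                                  result$aligned_post_image, pro_mask)
  rep <- structure(list(
    dice_by_organ = dice_by_organ,
    t3_fit_dice = fit_dice,
    volumes_ml = vols,
    volume_change_percent = vchange,
    max_deformation_mm = max(mag$data),
    max_deformation_at_mm = mag$origin + (as.numeric(loc) - 1) * mag$spacing,
    intensity_diff = list(max_percent = attr(idm, "max_percent"),
                          mean_percent = attr(idm, "mean_percent"),
                          argmax_mm = attr(idm, "argmax_mm")),
    provenance = result$provenance
  ), class = "quant_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    json <- list(dice_by_organ = as.list(rep$dice_by_organ),
                 t3_fit_dice = rep$t3_fit_dice,
                 volume_change_percent = as.list(rep$volume_change_percent),
                 max_deformation_mm = rep$max_deformation_mm,
                 max_deformation_at_mm = rep$max_deformation_at_mm)
    json$volumes_ml <- list(pre = as.list(vols["pre", ]),
                            post = as.list(vols["post", ]))
    json$intensity_diff <- rep$intensity_diff
    json$seed <- result$provenance$seed
    json$material <- unclass(result$provenance$material)
    jsonlite::write_json(json, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    df <- data.frame(organ = organs, dice = dice_by_organ,
                     pre_ml = vols["pre", ], post_ml = vols["post", ],
                     change_percent = vchange)
    write.csv(df, file.path(out_dir, "report.csv"), row.names = FALSE)
    write_volume(mag, file.path(out_dir, "t3_magnitude.nii.gz"))
    write_volume(idm, file.path(out_dir, "intensity_diff.nii.gz"))
  }
  rep
}

#' @export
print.quant_report <- function(x, ...) {
  cat("Quantification of treatment-induced change\n")
  cat("  Dice (pre vs corrected post):\n")
  for (org in names(x$dice_by_organ))
    cat(sprintf("    %-9s %.3f\n", org, x$dice_by_organ[[org]]))
  cat(sprintf("  stage-3 prostate surface fit Dice: %.3f\n", x$t3_fit_dice))
  cat(sprintf("  prostate volume: %.1f -> %.1f ml (%+.1f%%)\n",
              x$volumes_ml["pre", "prostate"], x$volumes_ml["post", "prostate"],
              x$volume_change_percent[["prostate"]]))
  cat(sprintf("  max treatment deformation: %.2f mm at (%s) mm\n",
              x$max_deformation_mm,
              paste(signif(x$max_deformation_at_mm, 4), collapse = ", ")))
  cat(sprintf("  intensity difference in prostate: mean %.1f%%, max %.1f%%\n",
              x$intensity_diff$mean_percent, x$intensity_diff$max_percent))
  invisible(x)
}
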