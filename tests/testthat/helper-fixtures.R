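# Shared fixtures, built lazily and cached for the whole test run.
# The desk-scale phantom (72 mm field of view at 1 mm isotropic) and its
# 3 mm FEM mesh are reused by many tests; building them once keeps the
# suite fast without any stored binary data.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

desk_spec <- function() phantom_spec(scale = 72 / 140)

desk_phantom <- function() {
  fixture("phantom", function() generate_phantom(desk_spec()))
}

desk_mesh <- function() {
  fixture("mesh", function() {
    build_mesh(desk_phantom()$labels, 3, 3, margin = 9)
  })
}

desk_stiffness <- function() {
  fixture("K", function() {
    assemble_stiffness(desk_mesh(), material_params(30, 0.45))
  })
}

desk_fem <- function() list(mesh = desk_mesh(), K = desk_stiffness())

# a small phantom for the (slower) intensity-based registration tests
small_phantom <- function() {
  fixture("small_phantom", function() generate_phantom(phantom_spec(scale = 0.4)))
}

# organ mask shortcut (internal helper is not exported)
mask_of <- function(labels, organ) {
  labels$data == unname(labels$dictionary[[organ]])
}

# cube label map helper: an n^3 mm cube of `label` inside a padded box
cube_labelmap <- function(n = 10, pad = 2, label = 1L, spacing = 1) {
  d <- as.integer(n + 2 * pad)
  a <- array(0L, c(d, d, d))
  idx <- (pad + 1):(pad + n)
  a[idx, idx, idx] <- label
  labelmap(a, rep(spacing, 3), rep(spacing / 2, 3))
}

# the calibrated synthetic deformation for one seed, cached by seed
desk_deformed <- function(seed) {
  fixture(paste0("deformed_", seed), function() {
    ph <- desk_phantom()
    sc <- calibrate_force_scale(ph, 0.65, seed = seed, fem = desk_fem())
    syn <- attr(sc, "deformation")
    field <- dispfield(syn$field$data * as.numeric(sc), ph$labels$spacing,
                       ph$labels$origin)
    list(scale = as.numeric(sc), field = field,
         labels = warp_image(ph$labels, field),
         image = warp_image(ph$image, field, interp = "linear"))
  })
}
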