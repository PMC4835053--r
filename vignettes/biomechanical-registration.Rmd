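---
title: "Biomechanically constrained registration of pre- and post-ablation prostate MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Biomechanically constrained registration of pre- and post-ablation prostate MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Focal laser ablation destroys prostate tumours thermally while sparing the
rest of the gland. Its effect shows on follow-up T2-weighted MRI as (a) a
local change in gland shape and (b) a local change in signal intensity.
Neither can be read off directly, because between the two scans the images
also differ by patient positioning and by deformation that the filling and
emptying of the bladder and rectum impose on the gland. `femablate`
decomposes the observed change into three transformations and removes the
first two:

1. **Linear alignment** (`register_linear`): translation, rotation and
   per-axis scaling, estimated by maximising the mutual information between
   the two volumes with a regular-step gradient ascent over a
   multiresolution pyramid.
2. **Organ-deformation removal** (`remove_organ_deformation`): a linear
   elastic finite element model built on the aligned post-treatment
   anatomy. Its bladder and rectum surfaces are driven toward their
   pre-treatment counterparts; the prostate carries no load and moves only
   through elastic transmission. Because the solve direction is
   post-to-pre, the computed field *is* the inverse organ deformation — no
   numeric field inversion is involved.
3. **Treatment deformation** (`estimate_treatment_deformation`): a second
   FEM built on the pre-treatment anatomy whose prostate surface is driven
   toward the corrected post-treatment prostate. The resulting field is
   the residual, treatment-attributable shape change; its magnitude map is
   the deformation heatmap, and the warped pre image and corrected post
   image form the spatially aligned pair for intensity comparison.

`fem_register()` runs the three stages and returns a classed fit with
`print`, `summary`, `coef`, `predict`, `residuals` and `plot` methods;
`build_report()` assembles Dice overlaps, organ volumes and change,
deformation statistics and the relative intensity-difference map.

## The elastic model

Tissue is modelled as a homogeneous, isotropic, linear elastic continuum
discretised into 8-node hexahedral elements with trilinear shape functions
and 2×2×2 Gauss quadrature. With nodal displacements $U$ (3 per node),
the stiffness system

$$ K\,U = F $$

is assembled from cube elements (for which the element matrix scales as
$E\,h$ with Young's modulus $E$ and edge $h$) and solved with BiCGStab.
The defaults are the soft-tissue operating point: $E = 30$ kPa and
Poisson's ratio $\nu = 0.45$ (near-incompressible; the value is a package
choice — the prostate-FEM literature brackets it but rarely states it).
Both are configurable via `material_params()`.

Nodal displacements become a dense voxel field by evaluating the element
shape functions at each voxel centre (`interpolate_displacements`). Two
alternative weightings are selectable: `inverse_distance`, and the
`as_printed` variant that weights corner nodes *proportionally* to their
distance (so a coincident node gets weight zero). The latter reproduces a
distance-weighting formulation sometimes written down in this area; we
regard it as a transcription of inverse-distance weighting and default to
the FEM-consistent trilinear scheme. All three normalise to a partition of
unity; the trilinear scheme reproduces affine fields exactly.

All images warp by backward sampling: the output voxel at centre $c$
samples the input at $c + d(c)$. Warp fields compose by resampling
(`compose_fields`) and can be inverted numerically by fixed-point
iteration (`invert_field`, 20 sweeps or 0.01 mm), though the pipeline
never needs the latter.

### Boundary conditions

The mesh covers the organ bounding box plus a background margin (default
9 mm). The far field must be anchored to remove rigid modes. Clamping
every face of the box over-constrains the interior: with a
near-incompressible material in a sealed box, bladder or rectal filling
cannot displace the gland the way it visibly does on real scans — in our
experiments the transmitted motion was several times too small, which
forces any calibration of the organ loads into an unphysical,
non-invertible regime. The default therefore clamps only the inferior and
superior faces, where tissue genuinely continues along the body axis, and
leaves the lateral faces traction-free (`fem_control(far_field =
"zfaces")`; `"all"` restores the sealed box).

### Driving modes and the modulus sweep

Surface loads originate from correspondences between organ surfaces. The
moving organ's boundary-voxel cloud (image resolution, which avoids the
staircase bias of the element-scale mesh boundary) is matched to the
target cloud by symmetric closest-point search, gated at 20 mm, and the
matched displacements are averaged onto the nearest organ-surface mesh
nodes. Matching, solving and re-matching iterates (iterated closest
point), and the organ-removal stage additionally rebuilds the model on the
corrected configuration and composes the fields (`organ_outer_iters`,
default 2), which removes the second-order error of solving on deformed
geometry.

Two ways of turning correspondences into loads are supported:

* **Prescribed displacement** (default): matched displacements become
  Dirichlet values. Robust and tolerance-free — and, for a homogeneous
  material, exactly independent of Young's modulus.
* **Force mode**: matched displacements become nodal forces through a
  spring constant fitted once per iteration *at the reference soft-tissue
  modulus* (30 kPa): the applied force is the least-squares multiple of
  the reference response that best reproduces the demanded surface
  displacements. Solving with a stiffer material then under-corrects by
  $E_{\mathrm{ref}}/E$ and a softer one over-corrects; steps are clamped
  to twice the current surface residual and the iterate with the smallest
  residual is kept. This is the only reading under which a Young's-modulus
  sensitivity of the recovery exists at all, and it is the mode the
  packaged modulus-sweep experiment uses.

### Solver

The constrained system (after master–slave elimination of hanging-node
constraints on adaptive meshes and elimination of Dirichlet DOFs) is SPD
and solved by BiCGStab preconditioned with a zero-fill incomplete Cholesky
factorisation (automatic Jacobi fallback on breakdown), relative residual
$10^{-6}$. On the experiment meshes this converges in roughly 10–30
iterations. A dense direct solve is available (`method = "direct"`) and
serves as the independent oracle in the tests.

## The phantom and its ground truth

`phantom_spec()` describes an analytic pelvis: a ~140 mm cubic field of
view holding a prostate ellipsoid (default semi-axes 23, 21, 22 mm; a
23 mm sphere reproduces the cohort's median gland volume of ~51 ml), a
large anterior–superior bladder and a distended posterior rectal tube,
each within 1–1.5 mm of the gland as in real pelvic anatomy — contact is
what lets organ motion transmit. Intensities are per-organ means plus
seeded Gaussian noise; no MRI physics (bias fields, coils, partial
volume) is simulated, so passing results say nothing about
intensity-driven failure modes on real acquisitions. A `scale` argument
shrinks the geometry for desk-scale work; the packaged experiments use
`scale = 72/140` (a 72 mm field of view at 1 mm isotropic voxels, inside
the 64–96 mm band we consider representative) with 3 mm elements.

The ground-truth organ deformation (`generate_synthetic_deformation`)
mirrors how such a truth is obtained from patient data: a seeded virtual
"post-like" configuration is drawn for each organ (a random rigid shift of
6–10 mm plus a mild anisotropic dilation, the rectal tube constrained
in-plane), surface forces are derived by the same spring matching the
pipeline uses, at the reference modulus, and the truth is the exact FEM
response to that force vector. Two properties follow by construction: the
truth field is exactly a solution of the package's own elastic model (so
inversion experiments isolate inversion error, not model mismatch), and it
is exactly linear in `force_scale`, which `calibrate_force_scale()`
exploits — one unit solve, then bracketing and bisection on the scaled
field until the prostate Dice between original and deformed phantom
reaches its target (0.65 ± 0.01 by default, the starting overlap of the
inversion experiment) with a monotonicity check during bracketing.

A purely free-form random force field would *not* be an appropriate
truth: it contains surface-motion components that no surface-matching
recovery can observe (the aperture problem), capping recovery far below
what is reported for anatomically derived deformations.

`embed_focal_lesion()` emulates the treatment effect: prescribed inward
radial displacements (cosine-tapered) on the FEM nodes inside a lesion
ball, elastic relaxation outside, the contraction scaled by bisection to a
target prostate volume loss, plus an intensity change in the ball. The
lesion ball defaults to 40% of the gland's equivalent radius.

## Packaged experiments

`experiment_e1()` runs the inversion-accuracy study: per seed, calibrate
the ground truth to starting Dice 0.65, deform the phantom, recover with
the organ-removal FEM in force mode, record the recovered prostate Dice.
Sweeping Young's modulus while the truth stays at the 30 kPa reference
reproduces the characteristic sensitivity curve: flat and high across the
biomechanical 20–120 kPa range, degrading toward 0.3 and 3000 kPa.
`experiment_e2()` builds the full synthetic chain — lesion, organ
deformation, rigid misalignment — runs `fem_register()` and compares the
recovered components with the generated truth.

Problem sizes are chosen for desk-scale runs: the 72 mm phantom meshes to
~11,000 elements at 3 mm, one recovery takes a few seconds, and the
20-repeat experiment completes in a few minutes. The default linear
misalignment in `experiment_e2()` is rigid: follow-up imaging on the same
scanner differs by positioning, and a 9-parameter intensity registration
estimated on organ-deformed anatomy trades scale against deformation, so
scale recovery is exercised separately in the unit tests.

## Quantification conventions

* Dice is `2|A∩B|/(|A|+|B|)`; two empty masks count as perfect overlap
  (with a warning).
* Organ volumes are voxel counts times voxel volume. Volume *change* is
  reported per case as `100·(post − pre)/pre`. Note that a cohort's
  "change of medians" differs from the median of per-case changes; for
  the published cohort medians (51.0 → 47.7 ml) the per-case formula
  gives −6.5% while the study text prints a 5.1% decrease — both
  derivable from the same volumes, and both left to the reader of the
  volumes table.
* The intensity-difference map is `100·|a − b| / reference` inside a mask;
  the default reference is the masked mean of the first image (robust to
  near-zero voxels), with a per-voxel reference selectable.

## Numerical details and degenerate inputs

* Coordinates: voxel indices are 0-based in formulas, 1-based in R; a
  voxel centre sits at `origin + index·spacing`; direction matrices are
  assumed identity (oblique acquisitions must be resampled upstream).
* All pipeline computation happens on a common 1 mm isotropic working
  grid (`resample_iso`).
* `locate_element` breaks ties on shared faces toward the lower element
  id; points outside the mesh yield `NULL` and voxels outside receive
  zero displacement.
* Adaptive meshing (octree subdivision of surface-straddling elements,
  `max_size` snapped to `min_size · 2^k`, 2:1 balanced) records
  hanging-node constraints as trilinear interpolations of the coarse
  element's corners; chained constraints are excluded by the balance.
  Results in the experiments use the uniform mesh — the reported
  operating point — and adaptivity is exercised by the unit tests.
* Constant images make the mutual-information histogram degenerate; MI is
  defined as 0 there, with a warning.
* Empty label maps are accepted with a warning but cannot be meshed.

## Known limitations

* Linear (small-strain) elasticity with a homogeneous modulus: large
  deformations are handled by iterating and composing, not by a
  finite-strain formulation; per-tissue moduli are not modelled (the
  study this follows reports that heterogeneity did not change its
  results).
* No contact mechanics: organs transmit through the mesh continuum.
* The phantom has piecewise-constant intensities plus noise; mutual
  information behaves much better on it than on real acquisitions.
* Identity direction cosines only; no DICOM, no 4D series.
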