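# femablate

Quantifying what focal laser ablation did to a prostate requires comparing
the pre- and post-treatment MRI — but the two scans also differ by patient
positioning and by whatever the bladder and rectum happened to be doing.
`femablate` separates these effects with a biomechanically constrained
registration pipeline and reports the treatment-attributable change in
gland shape, volume and signal intensity. It is aimed at researchers in
image-guided prostate therapy who have pre/post T2-weighted volumes with
organ segmentations (prostate, bladder, rectum) and want physically
plausible, reproducible treatment-response measures.

## The model

Writing the post-treatment voxel set as the pre-treatment one carried
through three transformations,

    C_post = T1( T2( T3(C_pre) ) ),

with `T1` the positioning change, `T2` the deformation imposed by the
surrounding organs and `T3` the treatment-induced change, the pipeline
estimates the inverses of the first two and isolates the third:

1. `T1^-1`: 9-parameter linear alignment (translation, rotation, per-axis
   scale) maximising mutual information with regular-step gradient ascent
   over a multiresolution pyramid.
2. `T2^-1`: a hexahedral linear-elastic finite element model (trilinear
   elements, `K U = F`, Young's modulus 30 kPa, Poisson ratio 0.45, solved
   with preconditioned BiCGStab) built on the aligned post anatomy. Its
   bladder and rectum surfaces are driven toward their pre-treatment
   counterparts by closest-point surface matching; the prostate carries no
   load and moves only by elastic transmission. Solving post-to-pre makes
   the result the inverse organ deformation directly.
3. `T3`: a second FEM on the pre anatomy drives the pre prostate surface
   onto the corrected post prostate. Its magnitude map `|T3(c) - c|` is
   the treatment deformation heatmap, and `T3(I_pre)` together with the
   corrected post image is the aligned pair for the relative
   intensity-difference map.

Everything is validated on a synthetic pelvic phantom whose ground-truth
deformations are themselves exact FEM solutions, so the inversion
experiment measures inversion error rather than model mismatch.

## Worked example

The end-to-end synthetic experiment builds a pre-treatment phantom,
implants a focal lesion calibrated to a 5 % gland-volume loss, deforms the
anatomy through the organ FEM, misaligns it rigidly, and then asks the
pipeline to undo all of it:

```r
library(femablate)
e2 <- experiment_e2(seed = 1, organ_dice = 0.8)
print(e2$report)
#> Quantification of treatment-induced change
#>   Dice (pre vs corrected post):
#>     prostate  0.941
#>     bladder   0.981
#>     rectum    0.985
#>   stage-3 prostate surface fit Dice: 0.966
#>   prostate volume: 6.0 -> 5.7 ml (-5.3%)
#>   max treatment deformation: 2.54 mm at (45.5, 40.5, 31.5) mm
#>   intensity difference in prostate: mean 10.2%, max 67.9%
```

Reading the numbers: after stages 1–2 the organ overlap is restored
(bladder/rectum Dice 0.98, prostate 0.94 — it started at 0.80 by
construction); the measured volume change (−5.3 %) recovers the implanted
−5 %; the deformation heatmap peaks 2.5 mm deep within 7 mm of the true
ablation site (`e2$truth$t3_peak_error_mm`); and the intensity difference
concentrates at the lesion. `plot(e2$result)` shows the heatmap slice;
`summary(e2$result)` rebuilds the report; `coef(e2$result)` returns the
recovered linear parameters.

The inversion-accuracy experiment itself is one call:

```r
e1 <- experiment_e1(youngs_sweep = 30, seeds = 1:20)
mean(e1$recovered_dice)   # ~0.93: organ deformation removed
plot_e1_sweep(experiment_e1(youngs_sweep = c(0.3, 3, 30, 300, 3000),
                            seeds = 1))
```

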