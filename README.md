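# carthick

Quantify knee articular cartilage thickness from segmentation label
volumes, partition it into the 14 WORMS anatomical regions, and run the
cohort statistics that describe how thickness differs across regions,
sexes, sides and ages.

Morphological thinning of knee cartilage is an early marker of
osteoarthritis, and region-resolved thickness baselines in healthy knees
are what an anomaly is measured against. `carthick` is aimed at
image-analysis researchers who already have bone + cartilage
segmentations (manual or from a network) as 3-D integer label volumes
with known voxel spacing, and who need reproducible per-region thickness
readings and the downstream population statistics.

## The method

For a bone--cartilage pair with masks \(B\) and \(C\):

1. compute exact signed Euclidean distance fields \(d_B\), \(d_C\)
   (negative inside, anisotropic spacing in mm);
2. take first-order gradients \(\nabla d_B\), \(\nabla d_C\);
3. classify each cartilage boundary voxel by the sign of
   \(\nabla d_B \cdot \nabla d_C\): negative = inner boundary (facing the
   bone), positive = outer boundary (articular surface);
4. thickness at an inner point = distance in mm to the nearest outer
   boundary point, read from a distance map seeded at the outer set;
5. average per region, where regions come from a geometric 14-region
   atlas (parasagittal medial/lateral split through the tibial or
   patellar centroid; anterior/central/posterior thirds along each
   bone's cartilage extent; the patella splits medial/lateral only).

Segmentation agreement is scored with the Dice similarity coefficient
\(DSC(A,B) = 2|A \cap B| / (|A| + |B|)\). Cohort tables are compared with
Tukey simultaneous 95% confidence intervals (studentized range, family
error controlled), and age effects are modelled as
`thickness ~ age * condition` (condition = sex or side), where the
interaction coefficient equals the difference between the two
condition-specific age slopes.

Because no scans ship with the package, a synthetic-data module supplies
(a) phantoms -- a cylindrical bone wearing a cartilage shell of known,
optionally angle-dependent thickness, and a three-bone knee covering all
14 regions -- and (b) cohort tables with the covariate structure of a
large healthy-knee study (n = 2,481; ages 15--64, mean 35, SD 10; 1,355
male / 1,126 female; 1,228 left / 1,253 right) whose 13 published region
means/SDs are the default calibration (the 14th, PL, is unpublished and
flagged uncalibrated).

## Worked example

```r
library(carthick)

# phantom with analytically known 3 mm shell at MR-like 0.5 x 0.5 x 3 mm
ph <- annulus_phantom(10, 3)
bp <- cartilage_thickness(ph$volume, "femur", "femoral_cartilage")
bp
#> <boundary_points> 896 inner, 1184 outer voxels; mean thickness 3.078 mm

# calibrated synthetic cohort and the region comparisons
tab <- make_cohort(cohort_spec())
tk  <- tukey_pairwise(tab, "region")
tk[tk$group1 %in% c("FMA", "FMC") & tk$group2 %in% c("TMA", "TMC"), ]
#>    group1 group2   diff     se    lwr    upr significant
#> 6     FMA    TMA 0.5853 0.0052 0.5680 0.6027        TRUE
#> 19    FMC    TMC 0.1507 0.0052 0.1333 0.1681        TRUE

fit_interaction_model(tab, "FMA", "sex")
#> Age x sex regression of FMA (n = 2481)
#>         term estimate      se        t       p      lwr     upr
#>  (Intercept)  2.06737 0.02272 91.00208 0.00000  2.02282 2.11192
#>          age -0.00035 0.00062 -0.56742 0.57048 -0.00156 0.00086
#>         sexM  0.00844 0.03093  0.27283 0.78501 -0.05221 0.06909
#>     age:sexM  0.00013 0.00084  0.15221 0.87904 -0.00152 0.00177
#> Verdict: thickness change with age is consistent between sex levels
```

The recovered 3.078 mm on the 3 mm phantom shows the sub-voxel accuracy
of the distance-map estimator; the femur-minus-tibia differences
(FMA−TMA ≈ 0.585 mm, FMC−TMC ≈ 0.151 mm with intervals excluding zero)
are the calibrated cohort reproducing the published femoral-vs-tibial
thickness gap; the regression verdict illustrates the consistency test:
with no configured slope difference between sexes, the interaction term
is (correctly) non-significant.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

regenerates the calibrated synthetic cohorts at the given seed, reruns
the package's Tukey and group-mean stages from scratch, and writes the
headline quantities (femur-vs-tibia Tukey differences, male-vs-female
region differences, the PM mean) as JSON.

See `vignettes/cartilage-thickness-methods.Rmd` for the model
assumptions, numerical conventions, and what the synthetic data does and
does not establish.
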