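# gmNodule

Geometric and morphological analysis of thyroid-nodule contours from
ultrasound, with an end-to-end benign/malignant classification pipeline:

1. **Contour geometry** — closed nodule boundaries (polygon annotations or
   binary masks) are measured for area, perimeter, convex hull, major/minor
   axes, orientation and bounding boxes.
2. **27 shape descriptors** — 19 geometric (convexity, solidity,
   compactness, rectangularity, roundness, eccentricity, circular and
   elliptic variance, …) plus 8 morphological (area, perimeter, aspect
   ratio, AP ratio, and perimeter ratios/differences against a related
   ellipse and circle).
3. **Fixed clinical selection** — 11 TIRADS-motivated features (solidity,
   orientation, roundness, axis lengths, bounding box, convex area, area,
   perimeter, aspect ratio, AP ratio) chosen for the visual attributes
   clinicians grade, not learned from data.
4. **Dataset I/O** — per-case annotation XML (coordinate-list dialect) and
   CSV feature tables that round-trip at full precision.
5. **Augmentation** — stochastic flips, rotations (canvas refit, never
   cropped) and Gaussian blur, used to balance a cohort to an exact
   per-class row count, byte-reproducibly for a given seed.
6. **Classification** — stratified 70–30 split and a 400-tree bootstrap
   random forest, reported as a confusion matrix with accuracy,
   sensitivity and specificity (positive = malignant).
7. **Synthetic shape generator** — a seeded polar shape model
   (ellipse × lobulation × band-limited spiculation) that produces labeled
   benign-like and malignant-like cohorts, so everything above runs and is
   tested without downloading any image data.

The package is S4 throughout: validated classes (`NoduleContour`,
`ShapeGeometry`, `FeatureVector`, `CaseRecord`, `LabeledFeatureTable`,
`ClassificationReport`, …), accessors and `show()` methods.

## Worked example

Parse the bundled annotation, extract features, and run the experiment on
a synthetic cohort. The numbers below are the actual output.

```r
library(gmNodule)

f <- system.file("extdata", "example_case.xml", package = "gmNodule")
case <- parseAnnotationXML(f)
case
#> CaseRecord example001 [original] - label: 1
#>   TIRADS: 4c
#>   contours: 1 | no embedded image

fv <- extractFeatures(caseContours(case)[[1]])
round(unlist(selectFeatures(fv, "tirads11")), 4)
#>          solidity       orientation         roundness major_axis_length
#>            0.9393          -76.4155            0.8715           88.6827
#> minor_axis_length      bounding_box       convex_area              area
#>           62.9847         5585.6541         4200.6588         3945.6246
#>         perimeter      aspect_ratio          ap_ratio
#>          248.1610            1.3495           15.8995
```

A solidity of 0.94 (boundary irregularity), aspect ratio 1.35
(taller-than-wide) and compactness 0.81 are all consistent with the
malignant-like TIRADS 4c annotation.

```r
cohort <- generateCohort(40, seed = 42)          # 40 benign + 40 malignant
lt <- buildFeatureTable(cohort)
runExperiment(lt, "tirads11", SplitConfig(seed = 42), ForestConfig(seed = 42))
#> ClassificationReport (positive = malignant)
#>   confusion: TN=12 FP=0 FN=0 TP=12
#>   accuracy:    1.0000
#>   sensitivity: 1.0000
#>   specificity: 1.0000
```

The synthetic classes are separable by construction (benign: smooth,
wider-than-tall; malignant: spiculated, taller-than-wide), so near-perfect
metrics are expected; a label permutation drops accuracy to chance
(~0.5), which the test suite checks.

## Command line

`inst/scripts/gmnodule` wraps the pipeline:

```sh
gmnodule simulate --n-per-class 50 --seed 7 --out-dir cohort
gmnodule augment  --in-dir cohort --target 200 --seed 7 --out-dir balanced
gmnodule extract  --in-dir balanced --out features.csv
gmnodule train    --features features.csv --arm tirads11 --seed 7
```

## Conventions worth knowing

- Pixel (i, j) (0-based) occupies the unit square [i, i+1) × [j, j+1) with
  center (i + 0.5, j + 0.5); masks are R matrices `[row = y, col = x]`;
  contour coordinates are x-right / y-down.
- Orientation is reported in the y-up frame in degrees within (−90, 90].
- Mask tracing takes the 0.5 level set of a lightly Gaussian-blurred mask
  (σ = 0.9 px), which removes the pixel staircase: a digitized r = 50 disk
  traces to within 0.8% of the true perimeter. See the vignette for the
  error analysis.
- The forest is configured with `splitCriterion = "entropy"`; the `ranger`
  backend uses Gini impurity for classification, which is recorded in the
  configuration and documented (the two are nearly always equivalent in
  practice).
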