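#' @import methods
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' Closed nodule boundary contour
#'
#' An ordered, closed boundary polygon in image pixel space. The first point
#' is not repeated at the end; closure is implicit. Coordinates follow the
#' raster convention: x to the right, y downwards, origin at the top-left
#' image corner, with pixel \eqn{(i, j)} occupying the unit square
#' \eqn{[i, i+1) \times [j, j+1)} so that its center sits at
#' \eqn{(i + 0.5, j + 0.5)}.
#'
#' @slot points numeric matrix with columns `x`, `y`; at least 3
#'   non-collinear vertices, consecutive duplicates removed.
#' @slot source character; `"polygon-annotation"` for contours read from
#'   coordinate lists, `"traced-from-mask"` for contours traced from binary
#'   rasters.
#' @slot imageSize integer vector `(width, height)` in pixels, or
#'   `integer(0)` when unknown.
#'
#' @seealso [NoduleContour()] for the validating constructor,
#'   [computeGeometry()] for derived measurements.
#' @exportClass NoduleContour
setClass("NoduleContour",
  representation(points = "matrix", source = "character",
                 imageSize = "integer"),
  prototype(source = "polygon-annotation", imageSize = integer(0))
)

setValidity("NoduleContour", function(object) {
  p <- object@points
  msg <- character(0)
  if (!is.numeric(p) || ncol(p) != 2L)
    return("points must be a numeric matrix with two columns (x, y)")
  if (nrow(p) < 3L)
    msg <- c(msg, "a contour needs at least 3 points")
  if (!all(is.finite(p)))
    msg <- c(msg, "contour coordinates must be finite")
  if (nrow(p) >= 3L && all(is.finite(p)) &&
      abs(.shoelace(p)) < .Machine$double.eps * max(1, max(abs(p)))^2)
    msg <- c(msg, "zero-area object: contour points are collinear")
  if (length(object@imageSize) > 0) {
    if (length(object@imageSize) != 2L || any(object@imageSize <= 0L))
      msg <- c(msg, "imageSize must be (width, height), both positive")
    else if (all(is.finite(p)) && nrow(p) > 0 &&
             (min(p) < 0 || max(p[, 1]) > object@imageSize[1] ||
              max(p[, 2]) > object@imageSize[2]))
      msg <- c(msg, "contour coordinates must lie within imageSize")
  }
  if (!object@source %in% c("polygon-annotation", "traced-from-mask"))
    msg <- c(msg, "source must be 'polygon-annotation' or 'traced-from-mask'")
  if (length(msg)) msg else TRUE
})

#' Base geometric measurements of a contour
#'
#' All raw measurements the shape-feature formulas consume, computed once
#' per contour by [computeGeometry()].
#'
#' @slot areaAn polygon area (shoelace), px^2.
#' @slot perimeterPn polygon arc length (sum of Euclidean segment lengths,
#'   closing segment included), px.
#' @slot hull convex hull of the contour vertices, a [NoduleContour-class].
#' @slot convexAreaAc,convexPerimeterPc hull area (px^2) and perimeter (px).
#' @slot filledArea number of pixels whose centers fall inside the polygon.
#' @slot centroid polygon (area) centroid `(c_x, c_y)`, px.
#' @slot majorAxis 2x2 matrix; rows are the two endpoints of the longest
#'   boundary-to-boundary chord.
#' @slot majorLen,minorLen major/minor axis lengths, px.
#' @slot minorAxis 2x2 matrix of minor-axis endpoints.
#' @slot orientationDeg major-axis angle, degrees in (-90, 90], measured
#'   counterclockwise from +x in a y-up mathematical frame.
#' @slot boxLn,boxWn length and width of the major-axis-oriented box
#'   (`boxLn >= boxWn`), px.
#' @slot alignedWidth,alignedDepth axis-aligned x-extent (width) and
#'   y-extent (depth) of the contour, px.
#' @slot bboxArea `majorLen * minorLen`, px^2.
#' @slot contour the source [NoduleContour-class] the measurements derive
#'   from.
#' @exportClass ShapeGeometry
setClass("ShapeGeometry",
  representation(contour = "NoduleContour",
                 areaAn = "numeric", perimeterPn = "numeric",
                 hull = "NoduleContour", convexAreaAc = "numeric",
                 convexPerimeterPc = "numeric", filledArea = "numeric",
                 centroid = "numeric", majorAxis = "matrix",
                 majorLen = "numeric", minorAxis = "matrix",
                 minorLen = "numeric", orientationDeg = "numeric",
                 boxLn = "numeric", boxWn = "numeric",
                 alignedWidth = "numeric", alignedDepth = "numeric",
                 bboxArea = "numeric")
)

setValidity("ShapeGeometry", function(object) {
  msg <- character(0)
  rel <- function(a, b) (a - b) / max(abs(a), abs(b), 1)
  if (rel(object@convexPerimeterPc, object@perimeterPn) > 1e-9)
    msg <- c(msg, "convex perimeter exceeds contour perimeter")
  if (rel(object@areaAn, object@convexAreaAc) > 1e-9)
    msg <- c(msg, "contour area exceeds convex area")
  if (object@minorLen > object@majorLen * (1 + 1e-12))
    msg <- c(msg, "minor axis longer than major axis")
  if (object@bboxArea != object@majorLen * object@minorLen)
    msg <- c(msg, "bboxArea must equal majorLen * minorLen exactly")
  if (!(object@orientationDeg > -90 && object@orientationDeg <= 90))
    msg <- c(msg, "orientation must lie in (-90, 90]")
  if (length(msg)) msg else TRUE
})

#' Reference shapes for perimeter-ratio features
#'
#' The ellipse and circle a nodule's perimeter is compared against, plus the
#' minimum-area enclosing rectangle. Built by [referenceShapes()].
#'
#' @slot minRectArea area of the minimum-area rotated enclosing rectangle,
#'   px^2.
#' @slot ellipseA,ellipseB reference-ellipse semi-axes (`ellipseA >=
#'   ellipseB`), px.
#' @slot ellipsePerimeter ellipse perimeter (Ramanujan-II approximation), px.
#' @slot circleRadius,circlePerimeter reference-circle radius and perimeter,
#'   px.
#' @exportClass ReferenceShapes
setClass("ReferenceShapes",
  representation(minRectArea = "numeric", ellipseA = "numeric",
                 ellipseB = "numeric", ellipsePerimeter = "numeric",
                 circleRadius = "numeric", circlePerimeter = "numeric")
)

setValidity("ReferenceShapes", function(object) {
  msg <- character(0)
  if (!(object@ellipseA >= object@ellipseB && object@ellipseB > 0))
    msg <- c(msg, "ellipse semi-axes must satisfy a >= b > 0")
  if (object@ellipsePerimeter <= 0 || object@circlePerimeter <= 0)
    msg <- c(msg, "reference perimeters must be positive")
  if (length(msg)) msg else TRUE
})

#' The 27 named geometric and morphological features of one nodule
#'
#' Holds the full feature inventory in its canonical order. Every entry is a
#' length-1 numeric except `centroid`, which holds the `(c_x, c_y)` pair and
#' counts as a single named feature; table writers flatten it to the two
#' columns `centroid_x`, `centroid_y`.
#'
#' @slot values named list of 27 entries in canonical order (see
#'   [gmFeatureNames()]).
#' @seealso [extractFeatures()], [selectFeatures()], [flattenFeatures()]
#' @exportClass FeatureVector
setClass("FeatureVector", representation(values = "list"))

setValidity("FeatureVector", function(object) {
  v <- object@values
  if (!identical(names(v), gmFeatureNames()))
    return("values must carry exactly the 27 canonical feature names, in order")
  lens <- vapply(v, length, 1L)
  want <- ifelse(names(v) == "centroid", 2L, 1L)
  if (!all(lens == want))
    return("every feature is a scalar except centroid, which is an (x, y) pair")
  if (!all(is.finite(unlist(v, use.names = FALSE))))
    return("all feature values must be finite")
  TRUE
})

#' One annotated ultrasound case
#'
#' A case couples an image (or its reference) with one or more ground-truth
#' nodule contours and a benign/malignant label, optionally via a TIRADS
#' category. Augmented copies record their provenance.
#'
#' @slot caseId character identifier, unique within a cohort.
#' @slot imageRef file path or other reference to the source image; may be
#'   empty when `image` is embedded.
#' @slot image numeric matrix (rows = y, columns = x) holding the image or
#'   mask, or `NULL`.
#' @slot contours list of [NoduleContour-class], one per annotated nodule.
#' @slot tirads TIRADS category as text (`"2"`, `"3"`, `"4a"`, `"4b"`,
#'   `"4c"`, `"5"`) or `character(0)` when absent.
#' @slot label integer 0 (benign) or 1 (malignant); `NA` until assigned.
#' @slot sourceTag `"original"` or `"augmented"`.
#' @slot sourceCaseId for augmented cases, the caseId they derive from.
#' @slot opLog list describing the augmentation operations applied.
#' @exportClass CaseRecord
setClass("CaseRecord",
  representation(caseId = "character", imageRef = "character",
                 image = "matrixOrNULL", contours = "list",
                 tirads = "character", label = "integer",
                 sourceTag = "character", sourceCaseId = "character",
                 opLog = "list"),
  prototype(imageRef = character(0), image = NULL, tirads = character(0),
            label = NA_integer_, sourceTag = "original",
            sourceCaseId = character(0), opLog = list())
)

setValidity("CaseRecord", function(object) {
  msg <- character(0)
  if (length(object@caseId) != 1L || !nzchar(object@caseId))
    msg <- c(msg, "caseId must be a single non-empty string")
  if (!all(vapply(object@contours, is, TRUE, "NoduleContour")))
    msg <- c(msg, "contours must all be NoduleContour objects")
  if (!is.na(object@label) && !object@label %in% c(0L, 1L))
    msg <- c(msg, "label must be 0 (benign) or 1 (malignant)")
  if (!object@sourceTag %in% c("original", "augmented"))
    msg <- c(msg, "sourceTag must be 'original' or 'augmented'")
  if (length(msg)) msg else TRUE
})

#' Labeled feature table
#'
#' Rows of flattened feature values plus provenance and a binary label:
#' columns `case_id`, `source_tag`, the 28 flattened feature columns
#' (centroid split into `centroid_x`, `centroid_y`) and `label`.
#'
#' @slot table the underlying `data.frame`.
#' @seealso [buildFeatureTable()], [writeFeatureTable()],
#'   [readFeatureTable()]
#' @exportClass LabeledFeatureTable
setClass("LabeledFeatureTable", representation(table = "data.frame"))

setValidity("LabeledFeatureTable", function(object) {
  tab <- object@table
  want <- featureTableColumns()
  if (!identical(names(tab), want))
    return(paste0("schema mismatch: expected columns ",
                  paste(want, collapse = ", ")))
  num <- flatFeatureNames()
  if (!all(vapply(tab[num], is.numeric, TRUE)))
    return("schema mismatch: feature columns must be numeric")
  if (anyNA(tab[c(num, "label")]))
    return("schema mismatch: missing values in feature or label columns")
  if (nrow(tab) > 0 && !all(tab$label %in% c(0L, 1L)))
    return("schema mismatch: label not binary")
  TRUE
})

#' Fitted random-forest nodule classifier
#'
#' Wraps the fitted ensemble together with the feature columns it was
#' trained on and its configuration, so that evaluation can verify schema
#' compatibility.
#'
#' @slot forest the fitted `ranger` object.
#' @slot featureNames character vector of training feature columns.
#' @slot config the [ForestConfig-class] used for training.
#' @exportClass NoduleForest
setClass("NoduleForest",
  representation(forest = "ANY", featureNames = "character",
                 config = "ANY")
)

#' Classification performance report
#'
#' Confusion matrix and the three clinical metrics, with malignant (label 1)
#' as the positive class. A metric whose denominator is empty (e.g.
#' specificity on a test set without benign cases) is `NA`, never silently
#' zero.
#'
#' @slot confusion named integer vector `(TN, FP, FN, TP)`.
#' @slot accuracy,sensitivity,specificity proportions in `[0, 1]` or `NA`.
#' @exportClass ClassificationReport
setClass("ClassificationReport",
  representation(confusion = "integer", accuracy = "numeric",
                 sensitivity = "numeric", specificity = "numeric")
)

setValidity("ClassificationReport", function(object) {
  if (!identical(names(object@confusion), c("TN", "FP", "FN", "TP")))
    return("confusion must be named (TN, FP, FN, TP)")
  ok <- function(x) is.na(x) || (x >= 0 && x <= 1)
  if (!ok(object@accuracy) || !ok(object@sensitivity) ||
      !ok(object@specificity))
    return("metrics must be proportions in [0, 1] or NA")
  TRUE
})

#' Augmentation configuration
#'
#' Probabilities and ranges of the stochastic flip/rotate/blur operations
#' used to balance a cohort, plus the augmentation target and seed. Defaults:
#' each operation fires with probability 0.5, rotations are drawn uniformly
#' from (-25, 25) degrees and blur sigmas from (0.5, 2) px.
#'
#' @slot pFlipH,pFlipV,pRotate,pBlur per-operation probabilities in `[0,1]`.
#' @slot rotateRangeDeg rotation angle range (lo, hi), degrees.
#' @slot blurSigmaRange Gaussian blur sigma range (lo, hi), px.
#' @slot targetPerClass rows per class after balancing.
#' @slot seed integer seed driving all stochastic draws.
#' @slot dropFeatureDuplicates if `TRUE`, blur-only augmented rows (whose
#'   contour, hence feature vector, duplicates the source exactly) are
#'   redrawn until a geometric op fires.
#' @exportClass AugmentationConfig
setClass("AugmentationConfig",
  representation(pFlipH = "numeric", pFlipV = "numeric", pRotate = "numeric",
                 pBlur = "numeric", rotateRangeDeg = "numeric",
                 blurSigmaRange = "numeric", targetPerClass = "integer",
                 seed = "integer", dropFeatureDuplicates = "logical"),
  prototype(pFlipH = 0.5, pFlipV = 0.5, pRotate = 0.5, pBlur = 0.5,
            rotateRangeDeg = c(-25, 25), blurSigmaRange = c(0.5, 2),
            targetPerClass = NA_integer_, seed = 1L,
            dropFeatureDuplicates = FALSE)
)

setValidity("AugmentationConfig", function(object) {
  p <- c(object@pFlipH, object@pFlipV, object@pRotate, object@pBlur)
  msg <- character(0)
  if (any(p < 0 | p > 1)) msg <- c(msg, "probabilities must lie in [0, 1]")
  r <- object@rotateRangeDeg
  if (length(r) != 2L || r[1] > r[2] || r[1] <= -180 || r[2] > 180)
    msg <- c(msg, "rotateRangeDeg must be (lo, hi) within (-180, 180]")
  b <- object@blurSigmaRange
  if (length(b) != 2L || b[1] > b[2] || b[1] < 0)
    msg <- c(msg, "blurSigmaRange must be (lo, hi) with lo >= 0")
  if (length(msg)) msg else TRUE
})

#' Train/test split configuration
#'
#' @slot testFraction held-out proportion, default 0.30.
#' @slot stratified preserve class proportions (default `TRUE`).
#' @slot groupAware keep all rows sharing a source case on one side of the
#'   split (default `FALSE`, which reproduces the augment-then-split
#'   procedure and its leakage).
#' @slot seed integer seed.
#' @exportClass SplitConfig
setClass("SplitConfig",
  representation(testFraction = "numeric", stratified = "logical",
                 groupAware = "logical", seed = "integer"),
  prototype(testFraction = 0.30, stratified = TRUE, groupAware = FALSE,
            seed = 1L)
)

setValidity("SplitConfig", function(object) {
  if (!(object@testFraction > 0 && object@testFraction < 1))
    return("testFraction must lie strictly between 0 and 1")
  TRUE
})

#' Random-forest configuration
#'
#' Defaults follow the reference protocol: 400 trees, entropy split
#' criterion, bootstrap resampling. The installed ranger backend implements
#' Gini impurity for classification; `splitCriterion` records the requested
#' rule (the two impurity measures select near-identical splits in
#' practice).
#'
#' @slot nTrees number of trees (default 400).
#' @slot splitCriterion requested impurity measure (default `"entropy"`).
#' @slot bootstrap bootstrap resampling flag (default `TRUE`).
#' @slot seed integer seed.
#' @exportClass ForestConfig
setClass("ForestConfig",
  representation(nTrees = "integer", splitCriterion = "character",
                 bootstrap = "logical", seed = "integer"),
  prototype(nTrees = 400L, splitCriterion = "entropy", bootstrap = TRUE,
            seed = 1L)
)

setValidity("ForestConfig", function(object) {
  if (is.na(object@nTrees) || object@nTrees < 1L)
    return("nTrees must be at least 1")
  TRUE
})

#' Synthetic nodule shape specification
#'
#' Parameterizes one synthetic contour: a base ellipse optionally decorated
#' with smooth lobulation and band-limited spiculation, mimicking the
#' TIRADS-relevant shape attributes (taller-than-wide orientation, margin
#' irregularity).
#'
#' @slot classLabel 0 (benign-like) or 1 (malignant-like).
#' @slot baseSemiAxes `(a, b)` px; `a` along x before rotation.
#' @slot rotationDeg rotation of the ellipse, degrees counterclockwise in
#'   the y-up frame.
#' @slot spiculeAmplitude radial spicule amplitude as a fraction of the
#'   local radius, in `[0, 0.5)`.
#' @slot spiculeCount dominant number of spicule lobes.
#' @slot lobulationAmplitude smooth low-order lobulation amplitude fraction.
#' @slot canvas `(width, height)` px of the output mask.
#' @slot seed integer seed.
#' @exportClass ShapeSpec
setClass("ShapeSpec",
  representation(classLabel = "integer", baseSemiAxes = "numeric",
                 rotationDeg = "numeric", spiculeAmplitude = "numeric",
                 spiculeCount = "integer", lobulationAmplitude = "numeric",
                 canvas = "integer", seed = "integer"),
  prototype(classLabel = 0L, baseSemiAxes = c(50, 50), rotationDeg = 0,
            spiculeAmplitude = 0, spiculeCount = 8L,
            lobulationAmplitude = 0, canvas = c(224L, 224L), seed = 1L)
)

setValidity("ShapeSpec", function(object) {
  msg <- character(0)
  if (any(object@baseSemiAxes <= 0))
    msg <- c(msg, "semi-axes must be positive")
  amp <- c(object@spiculeAmplitude, object@lobulationAmplitude)
  if (any(amp < 0 | amp >= 0.5))
    msg <- c(msg, "amplitudes must lie in [0, 0.5)")
  if (!object@classLabel %in% c(0L, 1L))
    msg <- c(msg, "classLabel must be 0 or 1")
  rmax <- max(object@baseSemiAxes) * (1 + sum(amp))
  if (rmax > min(object@canvas) / 2)
    msg <- c(msg, "shape does not fit the canvas after rotation")
  if (length(msg)) msg else TRUE
})
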