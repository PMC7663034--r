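#' Canonical feature names
#'
#' The 27 geometric and morphological feature names in their canonical
#' order: 19 geometric descriptors followed by 8 morphological ones.
#' `centroid` is a single named feature holding an (x, y) pair; everything
#' else is scalar.
#'
#' @return character vector of length 27.
#' @seealso [flatFeatureNames()] for the flattened 28-column form,
#'   [tiradsFeatureNames()] for the 11-feature clinical selection.
#' @export
gmFeatureNames <- function() {
  c("convex_hull", "convexity", "solidity", "elongation", "compactness",
    "rectangularity", "orientation", "roundness", "major_axis_length",
    "minor_axis_length", "eccentricity", "circular_variance",
    "elliptic_variance", "axis_ratio", "bounding_box", "centroid",
    "convex_area", "filled_area", "convex_perimeter",
    "area", "perimeter", "aspect_ratio", "ap_ratio",
    "tep_ratio", "tep_difference", "tcp_ratio", "tcp_difference")
}

#' @describeIn gmFeatureNames the 28 flattened column names (centroid split
#'   into `centroid_x`, `centroid_y`).
#' @export
flatFeatureNames <- function() {
  nm <- gmFeatureNames()
  i <- match("centroid", nm)
  c(nm[seq_len(i - 1)], "centroid_x", "centroid_y",
    nm[seq(i + 1, length(nm))])
}

#' @describeIn gmFeatureNames the full labeled-feature-table column set
#'   (provenance columns + flattened features + label).
#' @export
featureTableColumns <- function() {
  c("case_id", "source_tag", flatFeatureNames(), "label")
}

#' The 11 clinically selected features
#'
#' The fixed TIRADS-motivated selection of 11 significant features, in
#' canonical order. The selection targets the visual attributes clinicians
#' grade (shape, size, margin irregularity, orientation); it is a fixed
#' clinical choice, not a learned one.
#'
#' @return character vector of length 11.
#' @export
tiradsFeatureNames <- function() {
  c("solidity", "orientation", "roundness", "major_axis_length",
    "minor_axis_length", "bounding_box", "convex_area",
    "area", "perimeter", "aspect_ratio", "ap_ratio")
}

# radial profile: centroid-to-boundary distances with population mean/sd
.radialProfile <- function(p, centroid) {
  d <- sqrt((p[, 1] - centroid[1])^2 + (p[, 2] - centroid[2])^2)
  n <- length(d)
  mu <- mean(d)
  list(distances = d, mean = mu, sd = sqrt(sum((d - mu)^2) / n))
}

# Mahalanobis profile: boundary distances normalized by the covariance of
# the centered boundary coordinates (the fitted oval)
.mahalanobisProfile <- function(p, centroid) {
  v <- sweep(p, 2, centroid)
  C <- crossprod(v) / nrow(v)
  Ci <- solve(C)
  d <- sqrt(rowSums((v %*% Ci) * v))
  n <- length(d)
  mu <- mean(d)
  list(distances = d, mean = mu, sd = sqrt(sum((d - mu)^2) / n),
       covariance = C)
}

#' Geometric shape descriptors
#'
#' The 19 geometric features: hull vertex count, convexity
#' \eqn{P_c/P_n}, solidity \eqn{A_n/A_c}, elongation \eqn{W_n/L_n},
#' compactness \eqn{4\pi A_n/P_n^2}, rectangularity \eqn{A_n/A_r},
#' orientation, roundness \eqn{4\pi A_n/P_c^2}, major/minor axis lengths,
#' eccentricity \eqn{L_{ma}/L_{MA}}, circular variance
#' \eqn{\sigma_R/\mu_R}, elliptic variance \eqn{\sigma'_R/\mu'_R},
#' axis ratio \eqn{L_{MA}/L_{ma}}, bounding-box area
#' \eqn{L_{MA} \cdot L_{ma}}, centroid, convex area, filled area and
#' convex perimeter.
#'
#' @param geom a [ShapeGeometry-class].
#' @param refs the matching [ReferenceShapes-class].
#' @return named list of 19 entries (centroid is an (x, y) pair).
#' @export
geometricFeatures <- function(geom, refs) {
  if (geom@areaAn <= 0) stop("zero-area object")
  # equal-arc-length resampling keeps the radial profiles independent of
  # the annotation's vertex density and exactly invariant under scaling
  p <- .resampleBoundary(contourPoints(geom@contour))
  rad <- .radialProfile(p, geom@centroid)
  mah <- .mahalanobisProfile(p, geom@centroid)
  list(
    convex_hull = as.numeric(nContourPoints(geom@hull)),
    convexity = geom@convexPerimeterPc / geom@perimeterPn,
    solidity = geom@areaAn / geom@convexAreaAc,
    elongation = geom@boxWn / geom@boxLn,
    compactness = 4 * pi * geom@areaAn / geom@perimeterPn^2,
    rectangularity = geom@areaAn / refs@minRectArea,
    orientation = geom@orientationDeg,
    roundness = 4 * pi * geom@areaAn / geom@convexPerimeterPc^2,
    major_axis_length = geom@majorLen,
    minor_axis_length = geom@minorLen,
    eccentricity = geom@minorLen / geom@majorLen,
    circular_variance = rad$sd / rad$mean,
    elliptic_variance = mah$sd / mah$mean,
    axis_ratio = geom@majorLen / geom@minorLen,
    bounding_box = geom@bboxArea,
    centroid = geom@centroid,
    convex_area = geom@convexAreaAc,
    filled_area = geom@filledArea,
    convex_perimeter = geom@convexPerimeterPc
  )
}

#' Morphological shape descriptors
#'
#' The 8 morphological features: area \eqn{A_n}, perimeter \eqn{P_n},
#' aspect ratio \eqn{D/W} (axis-aligned depth over width, the
#' taller-than-wide sign), AP ratio \eqn{A_n/P_n}, and the perimeter
#' ratios/differences against the related ellipse (TEP) and the relevant
#' circle (TCP).
#'
#' @inheritParams geometricFeatures
#' @return named list of 8 scalar entries.
#' @export
morphologicalFeatures <- function(geom, refs) {
  if (geom@areaAn <= 0) stop("zero-area object")
  list(
    area = geom@areaAn,
    perimeter = geom@perimeterPn,
    aspect_ratio = geom@alignedDepth / geom@alignedWidth,
    ap_ratio = geom@areaAn / geom@perimeterPn,
    tep_ratio = geom@perimeterPn / refs@ellipsePerimeter,
    tep_difference = geom@perimeterPn - refs@ellipsePerimeter,
    tcp_ratio = geom@perimeterPn / refs@circlePerimeter,
    tcp_difference = geom@perimeterPn - refs@circlePerimeter
  )
}

#' Extract the full 27-feature vector of a contour
#'
#' Composes [computeGeometry()], [referenceShapes()],
#' [geometricFeatures()] and [morphologicalFeatures()] into the canonical
#' 27-entry [FeatureVector-class].
#'
#' @param contour a [NoduleContour-class].
#' @param ... configuration passed on to [computeGeometry()]
#'   (`minorAxisMode`, `angleTolDeg`) and [referenceShapes()]
#'   (`tcpReference`, `tepReference`).
#' @return a [FeatureVector-class].
#' @examples
#' theta <- seq(0, 2 * pi, length.out = 181)[-181]
#' disk <- NoduleContour(cbind(60 + 50 * cos(theta), 60 + 50 * sin(theta)))
#' fv <- extractFeatures(disk)
#' featureValues(fv)$compactness   # close to 1 for a disk
#' @export
extractFeatures <- function(contour, ...) {
  dots <- list(...)
  gArgs <- dots[names(dots) %in% c("minorAxisMode", "angleTolDeg")]
  rArgs <- dots[names(dots) %in% c("tcpReference", "tepReference")]
  geom <- do.call(computeGeometry, c(list(contour), gArgs))
  refs <- do.call(referenceShapes, c(list(geom), rArgs))
  vals <- c(geometricFeatures(geom, refs), morphologicalFeatures(geom, refs))
  new("FeatureVector", values = vals[gmFeatureNames()])
}

#' @describeIn extractFeatures accessor for the named value list of a
#'   [FeatureVector-class].
#' @param fv a `FeatureVector`.
#' @export
featureValues <- function(fv) {
  stopifnot(is(fv, "FeatureVector"))
  fv@values
}

#' Flatten a feature vector to 28 numeric columns
#'
#' Splits the centroid pair into `centroid_x`/`centroid_y` and returns a
#' named numeric vector matching [flatFeatureNames()].
#'
#' @param fv a [FeatureVector-class].
#' @return named numeric vector of length 28.
#' @export
flattenFeatures <- function(fv) {
  v <- featureValues(fv)
  out <- numeric(0)
  for (nm in names(v)) {
    if (nm == "centroid")
      out <- c(out, centroid_x = unname(v[[nm]][1]),
               centroid_y = unname(v[[nm]][2]))
    else out <- c(out, stats::setNames(unname(v[[nm]]), nm))
  }
  out
}

#' Apply the fixed clinical feature selection
#'
#' Returns the 11 TIRADS-motivated significant features (`"tirads11"`), the
#' complementary 16 (`"discounted16"`), or the full inventory
#' (`"global27"`), preserving canonical order within each set.
#'
#' @param fv a [FeatureVector-class] carrying all 27 entries.
#' @param mode one of `"tirads11"` (default), `"discounted16"`,
#'   `"global27"`.
#' @return named list of feature values.
#' @export
selectFeatures <- function(fv,
                           mode = c("tirads11", "discounted16", "global27")) {
  mode <- match.arg(mode)
  v <- featureValues(fv)
  missing <- setdiff(gmFeatureNames(), names(v))
  if (length(missing))
    stop("incomplete feature vector: missing ",
         paste(missing, collapse = ", "))
  keep <- switch(mode,
    tirads11 = tiradsFeatureNames(),
    discounted16 = setdiff(gmFeatureNames(), tiradsFeatureNames()),
    global27 = gmFeatureNames())
  if (mode == "tirads11") v[keep] else v[names(v) %in% keep]
}

#' @describeIn selectFeatures flattened column names of a selection mode
#'   (`tirads11` has 11 columns; `discounted16` has 17 since the centroid
#'   pair flattens to two; `global27` has 28).
#' @export
selectedColumnNames <- function(mode = c("tirads11", "discounted16",
                                         "global27")) {
  mode <- match.arg(mode)
  keep <- switch(mode,
    tirads11 = tiradsFeatureNames(),
    discounted16 = setdiff(gmFeatureNames(), tiradsFeatureNames()),
    global27 = gmFeatureNames())
  flat <- flatFeatureNames()
  if ("centroid" %in% keep)
    keep <- c(setdiff(keep, "centroid"), "centroid_x", "centroid_y")
  flat[flat %in% keep]
}
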