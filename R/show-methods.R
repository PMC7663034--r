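#' @describeIn NoduleContour compact display.
#' @param object a `NoduleContour`.
#' @export
setMethod("show", "NoduleContour", function(object) {
  p <- object@points
  cat("NoduleContour:", nrow(p), "points (", object@source, ")\n")
  cat(sprintf("  x: [%.2f, %.2f]  y: [%.2f, %.2f]\n",
              min(p[, 1]), max(p[, 1]), min(p[, 2]), max(p[, 2])))
  if (length(object@imageSize))
    cat("  image:", object@imageSize[1], "x", object@imageSize[2], "px\n")
})

#' @describeIn ShapeGeometry compact display.
#' @param object a `ShapeGeometry`.
#' @export
setMethod("show", "ShapeGeometry", function(object) {
  cat("ShapeGeometry\n")
  cat(sprintf("  area %.1f px^2, perimeter %.1f px (hull: %.1f, %.1f)\n",
              object@areaAn, object@perimeterPn, object@convexAreaAc,
              object@convexPerimeterPc))
  cat(sprintf("  axes %.1f x %.1f px, orientation %.1f deg\n",
              object@majorLen, object@minorLen, object@orientationDeg))
  cat(sprintf("  centroid (%.1f, %.1f), extents %.1f x %.1f px\n",
              object@centroid[1], object@centroid[2],
              object@alignedWidth, object@alignedDepth))
})

#' @describeIn FeatureVector compact display.
#' @param object a `FeatureVector`.
#' @export
setMethod("show", "FeatureVector", function(object) {
  cat("FeatureVector: 27 geometric and morphological features\n")
  v <- flattenFeatures(object)
  print(round(v, 4))
})

#' @describeIn CaseRecord compact display.
#' @param object a `CaseRecord`.
#' @export
setMethod("show", "CaseRecord", function(object) {
  cat("CaseRecord", object@caseId,
      sprintf("[%s]", object@sourceTag),
      "- label:", ifelse(is.na(object@label), "unassigned", object@label),
      "\n")
  if (length(object@tirads)) cat("  TIRADS:", object@tirads, "\n")
  cat("  contours:", length(object@contours),
      if (!is.null(object@image))
        sprintf("| image %d x %d px", ncol(object@image),
                nrow(object@image)) else "| no embedded image", "\n")
})

#' @describeIn LabeledFeatureTable compact display.
#' @param object a `LabeledFeatureTable`.
#' @export
setMethod("show", "LabeledFeatureTable", function(object) {
  tab <- object@table
  cat("LabeledFeatureTable:", nrow(tab), "rows x", ncol(tab), "columns\n")
  if (nrow(tab)) {
    cat("  labels: ", sum(tab$label == 0), " benign / ",
        sum(tab$label == 1), " malignant\n", sep = "")
    cat("  source: ", sum(tab$source_tag == "original"), " original / ",
        sum(tab$source_tag == "augmented"), " augmented\n", sep = "")
  }
})

#' @describeIn ClassificationReport compact display.
#' @param object a `ClassificationReport`.
#' @export
setMethod("show", "ClassificationReport", function(object) {
  cf <- object@confusion
  cat("ClassificationReport (positive = malignant)\n")
  cat(sprintf("  confusion: TN=%d FP=%d FN=%d TP=%d\n",
              cf["TN"], cf["FP"], cf["FN"], cf["TP"]))
  f <- function(z) if (is.na(z)) "undefined" else sprintf("%.4f", z)
  cat("  accuracy:   ", f(object@accuracy), "\n")
  cat("  sensitivity:", f(object@sensitivity), "\n")
  cat("  specificity:", f(object@specificity), "\n")
})
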