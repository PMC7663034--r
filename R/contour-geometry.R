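#' Construct a nodule contour
#'
#' Validating constructor for [NoduleContour-class]. Consecutive duplicate
#' vertices (and a repeated closing vertex) are removed before validation.
#'
#' @param points two-column matrix or data.frame of (x, y) vertex
#'   coordinates in pixels, ordered along the boundary; closure is implicit.
#' @param source provenance tag, `"polygon-annotation"` (default) or
#'   `"traced-from-mask"`.
#' @param imageSize optional `(width, height)` of the source image, px.
#' @return a validated `NoduleContour`.
#' @examples
#' sq <- NoduleContour(cbind(x = c(0, 10, 10, 0), y = c(0, 0, 10, 10)))
#' contourPoints(sq)
#' @export
NoduleContour <- function(points, source = "polygon-annotation",
                          imageSize = integer(0)) {
  p <- .cleanContour(points)
  new("NoduleContour", points = p, source = source,
      imageSize = as.integer(imageSize))
}

#' @describeIn NoduleContour vertex matrix accessor.
#' @param x a `NoduleContour`.
#' @export
contourPoints <- function(x) {
  stopifnot(is(x, "NoduleContour"))
  x@points
}

#' @describeIn NoduleContour number of vertices.
#' @export
nContourPoints <- function(x) nrow(contourPoints(x))

#' Read a binary mask from a raster file
#'
#' Reads a single-channel raster (PNG or TIFF; multi-channel images are
#' collapsed by their first channel) and binarizes it: nonzero = foreground.
#'
#' @param path file path.
#' @return integer matrix (rows = y from the top, columns = x) of 0/1.
#' @export
readMask <- function(path) {
  img <- EBImage::readImage(path)
  a <- EBImage::imageData(img)
  if (length(dim(a)) > 2) a <- a[, , 1]
  m <- t(a)     # EBImage stores (x, y); we use (row = y, col = x)
  (m > 0) + 0L
}

#' Trace the outer boundary of a mask
#'
#' Extracts the outer boundary of the single foreground object in a binary
#' mask as an ordered closed polygon. Holes are filled before tracing (the
#' ground truth is a nodule outline), and the boundary is traced at the
#' half-level crack between foreground and background pixel centers, so the
#' polygon area matches the pixel count closely and the contour/mask
#' round trip is near-lossless.
#'
#' @param mask numeric/integer/logical matrix (rows = y, columns = x);
#'   nonzero = foreground. Connected components smaller than 9 px are
#'   treated as noise and ignored.
#' @param keepLargest if `TRUE`, a mask with several foreground components
#'   keeps the largest one instead of failing.
#' @param traceSigma standard deviation (px) of the Gaussian applied to the
#'   binary mask before taking its 0.5 level set. The blur makes the level
#'   set sub-pixel accurate (for a straight edge the 0.5 crossing sits
#'   exactly on the true edge), suppressing the staircase that would
#'   otherwise inflate a digitized disk's perimeter by over 5%. Set to 0
#'   for the raw marching-squares polygon.
#' @return a [NoduleContour-class] with `source = "traced-from-mask"`.
#' @examples
#' m <- matrix(0L, 64, 64)
#' m[20:45, 15:50] <- 1L
#' ct <- maskToContour(m)
#' @export
maskToContour <- function(mask, keepLargest = FALSE, traceSigma = 0.9) {
  m <- (as.matrix(mask) > 0) + 0
  lab <- EBImage::bwlabel(EBImage::Image(t(m)))
  labm <- t(EBImage::imageData(lab))
  sizes <- tabulate(labm[labm > 0])
  keep <- which(sizes >= 9L)
  if (length(keep) == 0L) stop("no object: mask has no foreground component")
  if (length(keep) > 1L && !keepLargest)
    stop("ambiguous object: mask has ", length(keep),
         " foreground components (set keepLargest = TRUE to keep the largest)")
  sel <- keep[which.max(sizes[keep])]
  m <- (labm == sel) + 0
  filled <- t(EBImage::imageData(EBImage::fillHull(EBImage::Image(t(m)))))
  h <- nrow(filled); w <- ncol(filled)
  pad <- matrix(0, h + 4, w + 4)
  pad[3:(h + 2), 3:(w + 2)] <- filled
  if (traceSigma > 0)
    pad <- t(EBImage::imageData(EBImage::gblur(EBImage::Image(t(pad)),
                                               sigma = traceSigma)))
  # grid of padded pixel-center coordinates; padded pixel i maps to
  # original pixel i - 2, whose center is at i - 1.5
  xg <- (0:(w + 3)) - 1.5
  yg <- (0:(h + 3)) - 1.5
  cl <- grDevices::contourLines(xg, yg, t(pad), levels = 0.5)
  if (length(cl) == 0L) stop("no object: tracing produced no boundary")
  lens <- vapply(cl, function(ln) length(ln$x), 1L)
  ln <- cl[[which.max(lens)]]
  NoduleContour(cbind(ln$x, ln$y), source = "traced-from-mask",
                imageSize = c(w, h))
}

#' Rasterize a contour to a binary mask
#'
#' Fills the polygon interior on a `width x height` canvas: a pixel is
#' foreground when its center lies inside the polygon.
#'
#' @param contour a [NoduleContour-class].
#' @param size `(width, height)` of the canvas, px.
#' @return integer matrix (rows = y, columns = x) of 0/1.
#' @export
contourToMask <- function(contour, size) {
  p <- contourPoints(contour)
  w <- as.integer(size[1]); h <- as.integer(size[2])
  if (min(p) < 0 || max(p[, 1]) > w || max(p[, 2]) > h)
    stop("out of bounds: contour does not fit a ", w, "x", h, " canvas")
  m <- matrix(0L, h, w)
  xr <- max(0L, floor(min(p[, 1]))):min(w - 1L, ceiling(max(p[, 1])))
  yr <- max(0L, floor(min(p[, 2]))):min(h - 1L, ceiling(max(p[, 2])))
  centers <- as.matrix(expand.grid(x = xr + 0.5, y = yr + 0.5))
  inside <- .pointsInPolygon(centers, p)
  idx <- centers[inside, , drop = FALSE]
  m[cbind(idx[, 2] + 0.5, idx[, 1] + 0.5)] <- 1L
  m
}

#' Compute the base geometry of a contour
#'
#' Measures everything the shape-feature formulas consume: polygon area and
#' arc-length perimeter, convex hull (area/perimeter), filled pixel area,
#' area centroid, major axis (longest chord over all boundary-point pairs),
#' minor axis (longest chord perpendicular to the major axis within an
#' angular tolerance), orientation, oriented-box dimensions, axis-aligned
#' extents and the major-by-minor bounding-box area.
#'
#' For sparse polygon annotations the boundary is densified to roughly 1 px
#' vertex spacing before the axis searches so that chords between border
#' points, not only annotation vertices, are considered.
#'
#' @param contour a [NoduleContour-class].
#' @param minorAxisMode `"chord"` (longest perpendicular boundary chord,
#'   default) or `"projection"` (width of the projection perpendicular to
#'   the major axis).
#' @param angleTolDeg angular tolerance for the perpendicularity test in
#'   chord mode, degrees (default 2).
#' @return a [ShapeGeometry-class].
#' @examples
#' ct <- NoduleContour(cbind(c(0, 40, 40, 0), c(0, 0, 20, 20)))
#' g <- computeGeometry(ct)
#' g@majorLen   # ~ sqrt(40^2 + 20^2)
#' @export
computeGeometry <- function(contour,
                            minorAxisMode = c("chord", "projection"),
                            angleTolDeg = 2) {
  minorAxisMode <- match.arg(minorAxisMode)
  p <- contourPoints(contour)
  areaAn <- .polyArea(p)
  if (areaAn <= 0) stop("zero-area object")
  perim <- .polyPerimeter(p)
  hullP <- .convexHull(p)
  hull <- NoduleContour(hullP, source = contour@source)
  dense <- .densifyBoundary(p)
  major <- .majorAxisSearch(dense)
  axisDir <- major$endpoints[2, ] - major$endpoints[1, ]
  minor <- if (minorAxisMode == "chord")
    .minorAxisChord(dense, axisDir, angleTolDeg) else
    .minorAxisProjection(dense, axisDir)
  if (is.null(minor)) minor <- .minorAxisProjection(dense, axisDir)
  new("ShapeGeometry",
      contour = contour,
      areaAn = areaAn, perimeterPn = perim, hull = hull,
      convexAreaAc = .polyArea(hullP),
      convexPerimeterPc = .polyPerimeter(hullP),
      filledArea = .filledPixelCount(p),
      centroid = .polyCentroid(p),
      majorAxis = major$endpoints, majorLen = major$length,
      minorAxis = minor$endpoints, minorLen = minor$length,
      orientationDeg = .orientationDeg(major$endpoints),
      boxLn = major$length, boxWn = minor$length,
      alignedWidth = max(p[, 1]) - min(p[, 1]),
      alignedDepth = max(p[, 2]) - min(p[, 2]),
      bboxArea = major$length * minor$length)
}

# pixels whose centers fall inside the polygon, counted over its bbox
.filledPixelCount <- function(p) {
  xr <- floor(min(p[, 1])):ceiling(max(p[, 1]))
  yr <- floor(min(p[, 2])):ceiling(max(p[, 2]))
  centers <- as.matrix(expand.grid(x = xr + 0.5, y = yr + 0.5))
  sum(.pointsInPolygon(centers, p))
}

#' Minimum-area enclosing rectangle
#'
#' Area of the smallest enclosing rectangle over all orientations, found by
#' rotating calipers over the convex hull edges (the optimal rectangle has
#' one side collinear with a hull edge).
#'
#' @param hull a convex [NoduleContour-class] (e.g. the `hull` slot of a
#'   [ShapeGeometry-class]); a non-convex contour is replaced by its hull.
#' @return rectangle area, px^2.
#' @export
minimumAreaRectangle <- function(hull) {
  p <- .convexHull(contourPoints(hull))
  .minAreaRectangle(p)
}

#' Reference shapes for perimeter-ratio features
#'
#' Builds the comparison shapes used by the perimeter-ratio features: the
#' related ellipse (by default with semi-axes half the major and minor axis
#' lengths; alternatively the region-moments ellipse), the relevant circle
#' (by default the equal-area circle; alternatively the circle whose
#' diameter is the major axis), and the minimum-area enclosing rectangle.
#' The ellipse perimeter uses the Ramanujan-II approximation.
#'
#' @param geom a [ShapeGeometry-class].
#' @param tcpReference `"equal_area"` (default) or `"major_diameter"`.
#' @param tepReference `"axes_ellipse"` (default) or `"moments_ellipse"`.
#' @return a [ReferenceShapes-class].
#' @export
referenceShapes <- function(geom,
                           tcpReference = c("equal_area", "major_diameter"),
                           tepReference = c("axes_ellipse", "moments_ellipse")) {
  tcpReference <- match.arg(tcpReference)
  tepReference <- match.arg(tepReference)
  if (tepReference == "axes_ellipse") {
    a <- geom@majorLen / 2
    b <- geom@minorLen / 2
  } else {
    ev <- eigen(.polyCovariance(contourPoints(geom@contour)),
                symmetric = TRUE)$values
    a <- 2 * sqrt(max(ev)); b <- 2 * sqrt(min(ev))
  }
  r <- if (tcpReference == "equal_area") sqrt(geom@areaAn / pi) else
    geom@majorLen / 2
  new("ReferenceShapes",
      minRectArea = minimumAreaRectangle(geom@hull),
      ellipseA = a, ellipseB = b,
      ellipsePerimeter = .ramanujanPerimeter(a, b),
      circleRadius = r, circlePerimeter = 2 * pi * r)
}
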