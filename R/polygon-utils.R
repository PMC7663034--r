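# Internal polygon primitives shared by the geometry code. All polygons are
# n x 2 matrices of (x, y) vertices, open storage (first row not repeated).

# signed area, positive for counterclockwise order in the stored (y-down)
# frame's algebraic sense
.shoelace <- function(p) {
  n <- nrow(p)
  j <- c(2:n, 1L)
  sum(p[, 1] * p[j, 2] - p[j, 1] * p[, 2]) / 2
}

.polyArea <- function(p) abs(.shoelace(p))

.polyPerimeter <- function(p) {
  n <- nrow(p)
  j <- c(2:n, 1L)
  sum(sqrt(rowSums((p[j, , drop = FALSE] - p)^2)))
}

# area centroid ("center of gravity"), not the vertex mean
.polyCentroid <- function(p) {
  n <- nrow(p)
  j <- c(2:n, 1L)
  cr <- p[, 1] * p[j, 2] - p[j, 1] * p[, 2]
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps)
    stop("zero-area object: centroid undefined")
  c(sum((p[, 1] + p[j, 1]) * cr), sum((p[, 2] + p[j, 2]) * cr)) / (6 * a)
}

# central second moments (mu20, mu02, mu11) of the polygon interior,
# normalized by area (i.e. the region covariance)
.polyCovariance <- function(p) {
  n <- nrow(p)
  j <- c(2:n, 1L)
  x0 <- p[, 1]; y0 <- p[, 2]; x1 <- p[j, 1]; y1 <- p[j, 2]
  cr <- x0 * y1 - x1 * y0
  a <- sum(cr) / 2
  cx <- sum((x0 + x1) * cr) / (6 * a)
  cy <- sum((y0 + y1) * cr) / (6 * a)
  x0 <- x0 - cx; x1 <- x1 - cx; y0 <- y0 - cy; y1 <- y1 - cy
  cr <- x0 * y1 - x1 * y0
  mxx <- sum(cr * (x0^2 + x0 * x1 + x1^2)) / 12
  myy <- sum(cr * (y0^2 + y0 * y1 + y1^2)) / 12
  mxy <- sum(cr * (x0 * y1 + 2 * x0 * y0 + 2 * x1 * y1 + x1 * y0)) / 24
  s <- sign(a)
  matrix(c(mxx, mxy, mxy, myy) * s / abs(a), 2, 2)
}

# drop consecutive duplicate vertices (and a repeated closing vertex)
.cleanContour <- function(p, tol = 1e-9) {
  p <- as.matrix(p)
  storage.mode(p) <- "double"
  if (!all(is.finite(p)))
    stop("contour coordinates must be finite")
  if (nrow(p) > 1) {
    d <- sqrt(rowSums((p - p[c(nrow(p), 1:(nrow(p) - 1)), , drop = FALSE])^2))
    keep <- d > tol
    keep[1] <- TRUE
    p <- p[keep, , drop = FALSE]
    if (nrow(p) > 1 &&
        sqrt(sum((p[1, ] - p[nrow(p), ])^2)) <= tol)
      p <- p[-nrow(p), , drop = FALSE]
  }
  dimnames(p) <- list(NULL, c("x", "y"))
  p
}

# which of the query points (m x 2) fall inside the polygon
.pointsInPolygon <- function(pts, poly) {
  bnd <- rbind(poly, poly[1, , drop = FALSE])
  mgcv::in.out(bnd, as.matrix(pts))
}

# convex hull vertices, counterclockwise in the plotting sense
.convexHull <- function(p) {
  idx <- grDevices::chull(p)
  p[idx, , drop = FALSE]
}

# lexicographic comparison key for a chord's two endpoints: endpoints are
# ordered (x, then y) within the pair, pairs compared by the ordered tuple
.orderChord <- function(a, b) {
  if (a[1] < b[1] || (a[1] == b[1] && a[2] <= b[2])) rbind(a, b) else rbind(b, a)
}

.chordKey <- function(ep) c(ep[1, ], ep[2, ])

# longest boundary-to-boundary chord over all point pairs; ties broken by
# the lowest (x, then y) first endpoint, then the second
.majorAxisSearch <- function(p) {
  d <- as.matrix(stats::dist(p))
  dmax <- max(d)
  hits <- which(d == dmax & upper.tri(d), arr.ind = TRUE)
  best <- NULL
  for (k in seq_len(nrow(hits))) {
    ep <- .orderChord(p[hits[k, 1], ], p[hits[k, 2], ])
    if (is.null(best) || .lexLess(.chordKey(ep), .chordKey(best)))
      best <- ep
  }
  dimnames(best) <- list(NULL, c("x", "y"))
  list(length = dmax, endpoints = best)
}

.lexLess <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  FALSE
}

# longest chord whose direction is perpendicular to `axisDir` within
# `tolDeg`; returns NULL if no pair qualifies
.minorAxisChord <- function(p, axisDir, tolDeg) {
  u <- axisDir / sqrt(sum(axisDir^2))
  n <- nrow(p)
  dx <- outer(p[, 1], p[, 1], "-")
  dy <- outer(p[, 2], p[, 2], "-")
  len <- sqrt(dx^2 + dy^2)
  proj <- abs(dx * u[1] + dy * u[2])
  ok <- upper.tri(len) & len > 0 & proj <= len * sin(tolDeg * pi / 180)
  if (!any(ok)) return(NULL)
  lmax <- max(len[ok])
  hits <- which(ok & len == lmax, arr.ind = TRUE)
  best <- NULL
  for (k in seq_len(nrow(hits))) {
    ep <- .orderChord(p[hits[k, 2], ], p[hits[k, 1], ])
    if (is.null(best) || .lexLess(.chordKey(ep), .chordKey(best)))
      best <- ep
  }
  dimnames(best) <- list(NULL, c("x", "y"))
  list(length = lmax, endpoints = best)
}

# width of the point set projected onto the direction perpendicular to
# `axisDir`, with the extreme points as nominal endpoints
.minorAxisProjection <- function(p, axisDir) {
  u <- axisDir / sqrt(sum(axisDir^2))
  v <- c(-u[2], u[1])
  s <- p %*% v
  i <- which.min(s); j <- which.max(s)
  ep <- .orderChord(p[i, ], p[j, ])
  dimnames(ep) <- list(NULL, c("x", "y"))
  list(length = max(s) - min(s), endpoints = ep)
}

# resample polygon edges at roughly unit spacing so chord searches see
# border points, not just annotation vertices; vertex positions preserved
.densifyBoundary <- function(p, spacing = 1, maxPoints = 2000L) {
  n <- nrow(p)
  j <- c(2:n, 1L)
  seg <- sqrt(rowSums((p[j, , drop = FALSE] - p)^2))
  spacing <- max(spacing, sum(seg) / maxPoints)
  if (all(seg <= spacing)) return(p)
  pieces <- vector("list", n)
  for (i in seq_len(n)) {
    k <- max(1L, ceiling(seg[i] / spacing))
    t <- (seq_len(k) - 1L) / k
    pieces[[i]] <- cbind(p[i, 1] + t * (p[j[i], 1] - p[i, 1]),
                         p[i, 2] + t * (p[j[i], 2] - p[i, 2]))
  }
  out <- do.call(rbind, pieces)
  dimnames(out) <- list(NULL, c("x", "y"))
  out
}

# resample the closed boundary at n equally spaced arc-length positions,
# starting from the first vertex; the sample set depends only on the
# shape's normalized arc-length parametrization, so it is exactly
# equivariant under scaling and rigid motions
.resampleBoundary <- function(p, n = 720L) {
  m <- nrow(p)
  j <- c(2:m, 1L)
  seg <- sqrt(rowSums((p[j, , drop = FALSE] - p)^2))
  cum <- c(0, cumsum(seg))
  total <- cum[m + 1L]
  s <- total * (seq_len(n) - 1L) / n
  i <- findInterval(s, cum, rightmost.closed = TRUE)
  t <- (s - cum[i]) / seg[i]
  cbind(x = p[i, 1] + t * (p[j[i], 1] - p[i, 1]),
        y = p[i, 2] + t * (p[j[i], 2] - p[i, 2]))
}

# minimum-area enclosing rectangle by rotating calipers: the optimal
# rectangle has one side collinear with a hull edge
.minAreaRectangle <- function(hull) {
  n <- nrow(hull)
  if (n < 3) stop("zero-area object: degenerate hull")
  j <- c(2:n, 1L)
  best <- Inf
  for (i in seq_len(n)) {
    e <- hull[j[i], ] - hull[i, ]
    l <- sqrt(sum(e^2))
    if (l == 0) next
    u <- e / l
    v <- c(-u[2], u[1])
    su <- hull %*% u
    sv <- hull %*% v
    a <- (max(su) - min(su)) * (max(sv) - min(sv))
    if (a < best) best <- a
  }
  if (!is.finite(best) || best <= 0) stop("zero-area object: degenerate hull")
  best
}

# Ramanujan's second ellipse-perimeter approximation
.ramanujanPerimeter <- function(a, b) {
  h <- ((a - b) / (a + b))^2
  pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
}

# major-axis angle in degrees, counterclockwise from +x in a y-up frame,
# mapped into (-90, 90]
.orientationDeg <- function(endpoints) {
  dx <- endpoints[2, 1] - endpoints[1, 1]
  dy <- endpoints[2, 2] - endpoints[1, 2]
  ang <- atan2(-dy, dx) * 180 / pi   # y-down storage -> y-up angle
  ang <- ang %% 180
  if (ang > 90) ang <- ang - 180
  if (ang <= -90) ang <- ang + 180
  unname(ang)
}
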