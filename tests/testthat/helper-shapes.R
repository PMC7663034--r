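# Fixtures and independent oracles, all built in code.

# binary disk mask: pixel centers within `r` of the canvas center
diskMask <- function(size = 128L, r = 50) {
  cen <- size / 2
  x <- matrix(rep(seq_len(size) - 0.5, each = size), size, size)
  y <- matrix(rep(seq_len(size) - 0.5, times = size), size, size)
  ((x - cen)^2 + (y - cen)^2 <= r^2) + 0L
}

# polygonal circle contour (continuous, not digitized)
circleContour <- function(r = 50, cen = c(64, 64), n = 180L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  NoduleContour(cbind(cen[1] + r * cos(th), cen[2] + r * sin(th)))
}

rectContour <- function(w = 40, h = 20, at = c(10, 10)) {
  NoduleContour(cbind(at[1] + c(0, w, w, 0), at[2] + c(0, 0, h, h)))
}

ellipseContour <- function(a = 60, b = 30, cen = c(100, 100), n = 240L,
                           rotDeg = 0) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  phi <- rotDeg * pi / 180
  x <- a * cos(th); y <- b * sin(th)
  NoduleContour(cbind(cen[1] + x * cos(phi) - y * sin(phi),
                      cen[2] - (x * sin(phi) + y * cos(phi))))
}

# regular 5-pointed star (pentagram outline), outer radius R
starContour <- function(R = 50, cen = c(60, 60)) {
  rin <- R * cos(72 * pi / 180) / cos(36 * pi / 180)
  th <- pi / 2 + (0:9) * pi / 5
  rr <- rep(c(R, rin), 5)
  NoduleContour(cbind(cen[1] + rr * cos(th), cen[2] - rr * sin(th)))
}

# independent shoelace area / arc length, written from the textbook formula
oracleArea <- function(p) {
  n <- nrow(p); s <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    s <- s + p[i, 1] * p[j, 2] - p[j, 1] * p[i, 2]
  }
  abs(s) / 2
}

oraclePerimeter <- function(p) {
  n <- nrow(p); s <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    s <- s + sqrt(sum((p[j, ] - p[i, ])^2))
  }
  s
}

# brute-force O(N^2) longest-chord scan with the same tie policy as the
# production search (lowest (x, then y) first endpoint, then second), but
# an independent code path (outer products, no stats::dist)
oracleMajorAxis <- function(p) {
  dx <- outer(p[, 1], p[, 1], "-")
  dy <- outer(p[, 2], p[, 2], "-")
  d2 <- dx^2 + dy^2
  dmax <- max(d2)
  hits <- which(d2 == dmax, arr.ind = TRUE)
  best <- NULL; bestKey <- NULL
  for (k in seq_len(nrow(hits))) {
    pair <- p[c(hits[k, 1], hits[k, 2]), , drop = FALSE]
    o <- order(pair[, 1], pair[, 2])
    pair <- pair[o, , drop = FALSE]
    key <- c(pair[1, ], pair[2, ])
    if (is.null(best) || .lexBefore(key, bestKey)) {
      best <- pair; bestKey <- key
    }
  }
  list(length = sqrt(dmax), endpoints = unname(best))
}

.lexBefore <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  FALSE
}

# exact ellipse perimeter by numeric quadrature of the arc-length integral
oracleEllipsePerimeter <- function(a, b) {
  4 * stats::integrate(function(t) sqrt(a^2 * sin(t)^2 + b^2 * cos(t)^2),
                       0, pi / 2, rel.tol = 1e-12)$value
}

# random star-shaped test polygons (independent of the package generator)
randomBlob <- function(seed, n = 240L, rbase = 40, wobble = 0.25) {
  set.seed(seed)
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  k <- sample(2:9, 3)
  r <- rbase * (1 + wobble * (
    0.5 * sin(k[1] * th + runif(1, 0, 2 * pi)) +
    0.3 * sin(k[2] * th + runif(1, 0, 2 * pi)) +
    0.2 * sin(k[3] * th + runif(1, 0, 2 * pi))))
  NoduleContour(cbind(100 + r * cos(th), 100 + r * sin(th)))
}

dimensionlessFeatures <- function() {
  c("convexity", "solidity", "elongation", "compactness", "rectangularity",
    "roundness", "eccentricity", "circular_variance", "elliptic_variance",
    "axis_ratio", "tep_ratio", "tcp_ratio")
}

relErr <- function(a, b) abs(a - b) / pmax(abs(a), abs(b), .Machine$double.eps)
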