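#' Construct an augmentation configuration
#'
#' @param pFlipH,pFlipV,pRotate,pBlur per-operation firing probabilities.
#' @param rotateRangeDeg rotation range `(lo, hi)` in degrees; the angle is
#'   drawn uniformly from it.
#' @param blurSigmaRange Gaussian blur sigma range `(lo, hi)` in px.
#' @param targetPerClass rows per class after balancing.
#' @param seed integer seed for all stochastic draws.
#' @param dropFeatureDuplicates redraw blur-only augmentations (whose
#'   features duplicate the source exactly) until a geometric op fires.
#' @return an [AugmentationConfig-class].
#' @export
AugmentationConfig <- function(pFlipH = 0.5, pFlipV = 0.5, pRotate = 0.5,
                               pBlur = 0.5, rotateRangeDeg = c(-25, 25),
                               blurSigmaRange = c(0.5, 2),
                               targetPerClass = NA_integer_, seed = 1L,
                               dropFeatureDuplicates = FALSE) {
  new("AugmentationConfig", pFlipH = pFlipH, pFlipV = pFlipV,
      pRotate = pRotate, pBlur = pBlur,
      rotateRangeDeg = as.numeric(rotateRangeDeg),
      blurSigmaRange = as.numeric(blurSigmaRange),
      targetPerClass = as.integer(targetPerClass), seed = as.integer(seed),
      dropFeatureDuplicates = dropFeatureDuplicates)
}

.flipPairH <- function(image, contour) {
  w <- ncol(image)
  p <- contourPoints(contour)
  p[, 1] <- w - p[, 1]
  list(image = image[, rev(seq_len(w)), drop = FALSE],
       contour = NoduleContour(p[rev(seq_len(nrow(p))), , drop = FALSE],
                               source = contour@source,
                               imageSize = contour@imageSize))
}

.flipPairV <- function(image, contour) {
  h <- nrow(image)
  p <- contourPoints(contour)
  p[, 2] <- h - p[, 2]
  list(image = image[rev(seq_len(h)), , drop = FALSE],
       contour = NoduleContour(p[rev(seq_len(nrow(p))), , drop = FALSE],
                               source = contour@source,
                               imageSize = contour@imageSize))
}

# continuous rotation by `angleDeg` counterclockwise (y-up sense) about the
# image center; the canvas is refitted to the rotated image corners, never
# cropped, and contour coordinates are remapped exactly
.rotatePair <- function(image, contour, angleDeg) {
  h <- nrow(image); w <- ncol(image)
  th <- angleDeg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  cen <- c(w / 2, h / 2)
  toUp <- function(p) cbind(p[, 1], h - p[, 2])
  rot <- function(pu) sweep(sweep(pu, 2, cen) %*% t(R), 2, cen, "+")
  corners <- rot(toUp(cbind(c(0, w, w, 0), c(0, 0, h, h))))
  lo <- floor(apply(corners, 2, min))
  hi <- ceiling(apply(corners, 2, max))
  w2 <- as.integer(hi[1] - lo[1]); h2 <- as.integer(hi[2] - lo[2])
  # contour: forward map, then shift into the new canvas (y-down again)
  pu <- rot(toUp(contourPoints(contour)))
  pu <- sweep(pu, 2, lo)
  p2 <- cbind(pu[, 1], h2 - pu[, 2])
  # image: inverse map each output pixel center, bilinear interpolation
  gx <- (seq_len(w2) - 0.5) + lo[1]
  gy <- h2 - ((seq_len(h2) - 0.5)) + lo[2]     # y-up coords of output rows
  X <- matrix(gx, h2, w2, byrow = TRUE)
  Y <- matrix(gy, h2, w2)
  Xc <- X - cen[1]; Yc <- Y - cen[2]
  xs <- cos(th) * Xc + sin(th) * Yc + cen[1]   # R(-th) applied
  ys <- -sin(th) * Xc + cos(th) * Yc + cen[2]
  yd <- h - ys                                  # back to y-down coords
  # sample at pixel centers (col - 0.5, row - 0.5), zero outside
  at <- function(row, col) {
    ok <- col >= 1 & col <= w & row >= 1 & row <= h
    v <- numeric(length(row))
    v[ok] <- image[cbind(row[ok], col[ok])]
    v
  }
  c0 <- floor(xs - 0.5) + 1; r0 <- floor(yd - 0.5) + 1
  fx <- (xs - 0.5) - (c0 - 1); fy <- (yd - 0.5) - (r0 - 1)
  out <- matrix(
    at(r0, c0) * (1 - fx) * (1 - fy) + at(r0, c0 + 1) * fx * (1 - fy) +
    at(r0 + 1, c0) * (1 - fx) * fy + at(r0 + 1, c0 + 1) * fx * fy,
    h2, w2)
  list(image = out,
       contour = NoduleContour(p2, source = contour@source,
                               imageSize = c(w2, h2)))
}

.blurImage <- function(image, sigma) {
  t(EBImage::imageData(EBImage::gblur(EBImage::Image(t(image)),
                                      sigma = sigma)))
}

#' Stochastically augment one (image, contour) pair
#'
#' Each operation (horizontal flip, vertical flip, rotation, Gaussian blur)
#' fires independently with its configured probability, drawing from R's
#' current random number stream (seed it, e.g. with [withr::with_seed()],
#' for reproducibility; [balanceAugment()] does this for you). Geometric
#' operations are applied identically to image and contour — the contour is
#' remapped by the exact continuous transform — while blur touches only the
#' image. Rotation pads the canvas when needed; the nodule is never cropped.
#'
#' @param image numeric matrix (rows = y, columns = x).
#' @param contour the matching [NoduleContour-class].
#' @param config an [AugmentationConfig-class].
#' @return list with elements `image`, `contour` and `opLog` (named list:
#'   `flip_h`, `flip_v` logical; `rotate_deg`, `blur_sigma` numeric or
#'   `NA`).
#' @export
augmentCase <- function(image, contour, config = AugmentationConfig()) {
  p <- contourPoints(contour)
  if (min(p) < 0 || max(p[, 1]) > ncol(image) || max(p[, 2]) > nrow(image))
    stop("contour does not lie within the image bounds")
  repeat {
    doFh <- stats::runif(1) < config@pFlipH
    doFv <- stats::runif(1) < config@pFlipV
    doRot <- stats::runif(1) < config@pRotate
    doBlur <- stats::runif(1) < config@pBlur
    ang <- if (doRot) stats::runif(1, config@rotateRangeDeg[1],
                                   config@rotateRangeDeg[2]) else NA_real_
    sig <- if (doBlur) stats::runif(1, config@blurSigmaRange[1],
                                    config@blurSigmaRange[2]) else NA_real_
    if (!config@dropFeatureDuplicates || doFh || doFv || doRot) break
  }
  if (doFh) { z <- .flipPairH(image, contour); image <- z$image; contour <- z$contour }
  if (doFv) { z <- .flipPairV(image, contour); image <- z$image; contour <- z$contour }
  if (doRot) { z <- .rotatePair(image, contour, ang); image <- z$image; contour <- z$contour }
  if (doBlur) image <- .blurImage(image, sig)
  list(image = image, contour = contour,
       opLog = list(flip_h = doFh, flip_v = doFv, rotate_deg = ang,
                    blur_sigma = sig))
}

# image of a case, rasterized from its first contour when not embedded
.caseImage <- function(case) {
  if (!is.null(case@image)) return(case@image)
  ct <- case@contours[[1]]
  size <- if (length(ct@imageSize)) ct@imageSize else {
    p <- contourPoints(ct)
    c(ceiling(max(p[, 1])) + 2L, ceiling(max(p[, 2])) + 2L)
  }
  contourToMask(ct, size) + 0
}

#' Balance and enlarge a cohort by augmentation
#'
#' Retains every original (case, contour) row and tops each class up to
#' exactly `targetPerClass` rows with stochastically augmented copies:
#' source cases are drawn uniformly from the class and transformed by
#' [augmentCase()]. All randomness comes from one stream seeded with the
#' config seed, so identical inputs and config give byte-identical cohorts.
#'
#' @param cases list of labeled [CaseRecord-class].
#' @param config an [AugmentationConfig-class] with `targetPerClass` set;
#'   the target must be at least the largest original per-class row count.
#' @return list of [CaseRecord-class]: the originals followed by
#'   single-contour augmented records tagged with `sourceTag =
#'   "augmented"`, their `sourceCaseId` and an `opLog`.
#' @examples
#' cohort <- generateCohort(3, seed = 1)
#' bigger <- balanceAugment(cohort,
#'   AugmentationConfig(targetPerClass = 5L, seed = 9L))
#' table(vapply(bigger, caseLabel, 1L))
#' @export
balanceAugment <- function(cases, config) {
  if (is.na(config@targetPerClass))
    stop("config must set targetPerClass")
  labels <- vapply(cases, caseLabel, 1L)
  if (anyNA(labels)) stop("every case must be labeled before balancing")
  nrows <- vapply(cases, function(cs) length(cs@contours), 1L)
  target <- config@targetPerClass
  for (cls in c(0L, 1L)) {
    if (!any(labels == cls)) stop("need at least one case of class ", cls)
    if (sum(nrows[labels == cls]) > target)
      stop("targetPerClass (", target, ") is below the original row count ",
           "of class ", cls, " (", sum(nrows[labels == cls]), ")")
  }
  out <- cases
  withr::with_seed(config@seed, {
    for (cls in c(0L, 1L)) {
      idx <- which(labels == cls)
      units <- do.call(rbind, lapply(idx, function(i)
        data.frame(case = i, contour = seq_along(cases[[i]]@contours))))
      need <- target - sum(nrows[idx])
      for (k in seq_len(need)) {
        u <- units[sample.int(nrow(units), 1L), ]
        src <- cases[[u$case]]
        aug <- augmentCase(.caseImage(src), src@contours[[u$contour]],
                           config)
        out[[length(out) + 1L]] <- CaseRecord(
          caseId = paste0(src@caseId, "_aug", cls, "_", k),
          contours = aug$contour, label = cls, tirads = src@tirads,
          image = aug$image, sourceTag = "augmented",
          sourceCaseId = src@caseId, opLog = aug$opLog)
      }
    }
  })
  out
}
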