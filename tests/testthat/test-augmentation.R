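test_that("flips are exact coordinate maps on image and contour", {
  img <- matrix(0, 50, 70); img[10:20, 15:30] <- 1
  ct <- NoduleContour(cbind(c(15, 30, 30, 15), c(9, 9, 20, 20)))
  fh <- gmNodule:::.flipPairH(img, ct)
  expect_equal(sum(fh$image), sum(img))
  expect_equal(sort(contourPoints(fh$contour)[, 1]), sort(70 - c(15, 30, 30, 15)))
  expect_equal(contourPoints(fh$contour)[, 2], rev(c(9, 9, 20, 20)))
  fv <- gmNodule:::.flipPairV(img, ct)
  expect_equal(sort(contourPoints(fv$contour)[, 2]), sort(50 - c(9, 9, 20, 20)))
  # double flip restores the original exactly
  fhh <- gmNodule:::.flipPairH(fh$image, fh$contour)
  expect_identical(fhh$image, img)
  expect_equal(contourPoints(fhh$contour), contourPoints(ct))
})

test_that("rotation maps the contour exactly and refits the canvas", {
  img <- matrix(0, 60, 60); img[21:40, 21:40] <- 1  # pixels y,x in [20, 40)
  ct <- rectContour(20, 20, at = c(20, 20))
  z <- gmNodule:::.rotatePair(img, ct, 30)
  p0 <- contourPoints(ct); p1 <- contourPoints(z$contour)
  # lengths are preserved exactly by the rigid map
  d0 <- sqrt(sum((p0[2, ] - p0[1, ])^2))
  d1 <- sqrt(sum((p1[2, ] - p1[1, ])^2))
  expect_equal(d1, d0, tolerance = 1e-12)
  expect_lt(relErr(gmNodule:::.polyArea(p1), 400), 1e-12)
  # nothing is cropped: the contour fits in the new canvas
  expect_gte(min(p1), 0)
  expect_lte(max(p1[, 1]), ncol(z$image))
  expect_lte(max(p1[, 2]), nrow(z$image))
  # bilinear resampling preserves total intensity closely
  expect_lt(relErr(sum(z$image), sum(img)), 0.05)
  # the rotated image mass sits inside the rotated contour region
  m1 <- contourToMask(z$contour, c(ncol(z$image), nrow(z$image)))
  expect_gt(sum(z$image * m1) / sum(z$image), 0.95)
})

test_that("a 45-degree rotation enlarges the canvas, never crops", {
  img <- matrix(1, 40, 40)
  ct <- rectContour(40, 40, at = c(0, 0))
  z <- gmNodule:::.rotatePair(img, ct, 45)
  expect_gte(ncol(z$image), ceiling(40 * sqrt(2)))
  expect_gte(nrow(z$image), ceiling(40 * sqrt(2)))
  expect_lt(relErr(sum(z$image), 1600), 0.02)
})

test_that("blur preserves image mass and leaves geometry alone", {
  img <- matrix(0, 64, 64); img[24:40, 24:40] <- 1
  b <- gmNodule:::.blurImage(img, 1.5)
  expect_equal(dim(b), dim(img))
  expect_lt(relErr(sum(b), sum(img)), 0.01)
  expect_gt(max(abs(b - img)), 0.01)   # it did something
})

test_that("augmentCase logs exactly the operations it applied", {
  img <- matrix(0, 64, 64); img[20:44, 20:44] <- 1
  ct <- rectContour(24, 24, at = c(20, 20))
  cfgAll <- AugmentationConfig(pFlipH = 1, pFlipV = 1, pRotate = 1, pBlur = 1)
  z <- withr::with_seed(5, augmentCase(img, ct, cfgAll))
  expect_true(z$opLog$flip_h); expect_true(z$opLog$flip_v)
  expect_true(is.finite(z$opLog$rotate_deg))
  expect_gte(z$opLog$rotate_deg, -25); expect_lte(z$opLog$rotate_deg, 25)
  expect_true(is.finite(z$opLog$blur_sigma))
  cfgNone <- AugmentationConfig(pFlipH = 0, pFlipV = 0, pRotate = 0,
                                pBlur = 0)
  z0 <- withr::with_seed(5, augmentCase(img, ct, cfgNone))
  expect_identical(z0$image, img)
  expect_equal(contourPoints(z0$contour), contourPoints(ct))
  expect_false(z0$opLog$flip_h)
  expect_true(is.na(z0$opLog$rotate_deg))
  bad <- NoduleContour(cbind(c(50, 80, 80), c(10, 10, 40)))
  expect_error(augmentCase(img, bad, cfgAll), "image bounds")
})

test_that("dropFeatureDuplicates redraws blur-only augmentations", {
  img <- matrix(0, 64, 64); img[20:44, 20:44] <- 1
  ct <- rectContour(24, 24, at = c(20, 20))
  cfg <- AugmentationConfig(pFlipH = 0.2, pFlipV = 0.2, pRotate = 0.2,
                            pBlur = 0.9, dropFeatureDuplicates = TRUE)
  withr::with_seed(31, {
    for (i in 1:25) {
      z <- augmentCase(img, ct, cfg)
      expect_true(z$opLog$flip_h || z$opLog$flip_v ||
                    is.finite(z$opLog$rotate_deg))
    }
  })
})

test_that("augmented features change but dimensionless ones survive flips", {
  ct <- randomBlob(21)
  img <- contourToMask(ct, c(200, 200)) + 0
  cfg <- AugmentationConfig(pFlipH = 1, pFlipV = 0, pRotate = 0, pBlur = 0)
  z <- withr::with_seed(1, augmentCase(img, ct, cfg))
  v0 <- flattenFeatures(extractFeatures(ct))
  v1 <- flattenFeatures(extractFeatures(z$contour))
  dl <- dimensionlessFeatures()
  # mirroring reverses the boundary traversal, shifting the equal-arc
  # resampling start by one vertex; everything agrees to ~1e-4
  expect_equal(v1[dl], v0[dl], tolerance = 1e-3)
  expect_equal(unname(v1["area"]), unname(v0["area"]), tolerance = 1e-9)
  # mirroring flips the orientation sign (away from the 0/90 fixed points)
  if (abs(v0["orientation"]) > 2 && abs(abs(v0["orientation"]) - 90) > 2)
    expect_equal(unname(v1["orientation"]), -unname(v0["orientation"]),
                 tolerance = 0.1)
})

test_that("balanceAugment reaches the exact per-class target", {
  cohort <- generateCohort(2, seed = 11)     # 2 benign + 2 malignant
  cfg <- AugmentationConfig(targetPerClass = 6L, seed = 4L)
  out <- balanceAugment(cohort, cfg)
  labs <- vapply(out, caseLabel, 1L)
  rows <- vapply(out, function(cs) length(cs@contours), 1L)
  expect_identical(sum(rows[labs == 0L]), 6L)
  expect_identical(sum(rows[labs == 1L]), 6L)
  # originals retained verbatim, augmented rows tagged and traceable
  expect_identical(out[seq_along(cohort)], cohort)
  aug <- out[-seq_along(cohort)]
  expect_true(all(vapply(aug, function(cs) cs@sourceTag, "") == "augmented"))
  srcIds <- vapply(aug, function(cs) cs@sourceCaseId, "")
  expect_true(all(srcIds %in% vapply(cohort, function(cs) cs@caseId, "")))
  expect_true(all(vapply(aug, function(cs) length(cs@opLog) > 0, TRUE)))
  # identifiers stay unique
  expect_false(anyDuplicated(vapply(out, function(cs) cs@caseId, "")) > 0)
})

test_that("balanceAugment is deterministic and validates its inputs", {
  cohort <- generateCohort(2, seed = 11)
  cfg <- AugmentationConfig(targetPerClass = 5L, seed = 7L)
  a <- balanceAugment(cohort, cfg)
  b <- balanceAugment(cohort, cfg)
  expect_identical(a, b)
  c2 <- balanceAugment(cohort, AugmentationConfig(targetPerClass = 5L,
                                                  seed = 8L))
  expect_false(identical(a, c2))
  expect_error(balanceAugment(cohort, AugmentationConfig(seed = 1L)),
               "targetPerClass")
  expect_error(balanceAugment(cohort,
    AugmentationConfig(targetPerClass = 1L, seed = 1L)), "below the original")
  unlabeled <- cohort
  unlabeled[[1]]@label <- NA_integer_
  expect_error(balanceAugment(unlabeled, cfg), "labeled")
})
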