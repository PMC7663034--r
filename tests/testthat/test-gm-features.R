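test_that("the feature inventory has 27 names and 11 selected names", {
  expect_length(gmFeatureNames(), 27L)
  expect_length(unique(gmFeatureNames()), 27L)
  expect_length(tiradsFeatureNames(), 11L)
  expect_true(all(tiradsFeatureNames() %in% gmFeatureNames()))
  expect_length(flatFeatureNames(), 28L)
  expect_length(featureTableColumns(), 31L)  # 2 provenance + 28 + label
})

test_that("a feature vector carries all 27 entries in canonical order", {
  fv <- extractFeatures(circleContour(50))
  expect_s4_class(fv, "FeatureVector")
  expect_identical(names(featureValues(fv)), gmFeatureNames())
  fl <- flattenFeatures(fv)
  expect_identical(names(fl), flatFeatureNames())
  expect_true(all(is.finite(fl)))
})

test_that("disk features sit at the circular limit", {
  v <- featureValues(extractFeatures(circleContour(50)))
  expect_lt(abs(v$compactness - 1), 0.01)
  expect_lt(abs(v$roundness - 1), 0.01)
  expect_lt(abs(v$convexity - 1), 0.001)
  expect_lt(abs(v$solidity - 1), 0.001)
  expect_lt(abs(v$eccentricity - 1), 0.02)
  expect_lt(v$circular_variance, 0.01)
  expect_lt(v$elliptic_variance, 0.01)
  expect_lt(abs(v$rectangularity - pi / 4), 0.01)
  expect_lt(abs(v$tcp_ratio - 1), 0.01)
  expect_lt(abs(v$tep_ratio - 1), 0.02)
  expect_equal(unname(v$centroid), c(64, 64), tolerance = 0.01)
})

test_that("axis-aligned rectangle features match hand calculations", {
  v <- featureValues(extractFeatures(rectContour(40, 20)))
  expect_equal(v$area, 800)
  expect_equal(v$perimeter, 120)
  expect_equal(v$solidity, 1)
  expect_equal(v$convexity, 1)
  expect_equal(v$aspect_ratio, 0.5)            # depth 20 / width 40
  expect_equal(v$ap_ratio, 800 / 120)
  expect_equal(v$compactness, 4 * pi * 800 / 120^2, tolerance = 1e-12)
  expect_gte(v$rectangularity, 0.97)
  expect_lt(abs(v$major_axis_length - sqrt(2000)), 1.5)
  # tall rectangle flips the aspect ratio above 1
  vt <- featureValues(extractFeatures(rectContour(20, 40)))
  expect_equal(vt$aspect_ratio, 2)
})

test_that("2:1 ellipse features match the analytic ellipse", {
  v <- featureValues(extractFeatures(ellipseContour(60, 30)))
  expect_lt(abs(v$eccentricity - 0.5), 0.05)
  expect_lt(abs(v$axis_ratio - 2), 0.2)
  expect_lt(abs(v$tep_ratio - 1), 0.03)
  expect_lt(relErr(v$major_axis_length, 120), 0.02)
  expect_lt(relErr(v$minor_axis_length, 60), 0.03)
  expect_lt(relErr(v$area, pi * 60 * 30), 0.01)
  expect_lt(relErr(v$rectangularity, pi / 4), 0.03)
  expect_lt(abs(v$aspect_ratio - 0.5), 0.03)
  # rotated to vertical: taller than wide
  vv <- featureValues(extractFeatures(ellipseContour(60, 30, rotDeg = 90)))
  expect_lt(abs(vv$aspect_ratio - 2), 0.1)
})

test_that("a spiculated star scores low solidity and convexity", {
  v <- featureValues(extractFeatures(starContour(50)))
  # exact pentagram: A_star/A_hull and P_hull/P_star from the vertex radii
  expect_lt(v$solidity, 0.80)
  expect_lt(v$convexity, 0.95)
  expect_lt(v$compactness, 0.5)
  expect_equal(v$convex_hull, 5)
  # roundness ignores boundary crenellation; it exceeds compactness here
  expect_gt(v$roundness, v$compactness)
})

test_that("exact algebraic identities hold among the features", {
  for (ct in list(circleContour(50), rectContour(40, 20),
                  ellipseContour(60, 30, rotDeg = 25), starContour(50))) {
    v <- featureValues(extractFeatures(ct))
    expect_equal(v$compactness, v$roundness * v$convexity^2,
                 tolerance = 1e-9)
    expect_equal(v$tcp_ratio, 1 / sqrt(v$compactness), tolerance = 1e-9)
    expect_equal(v$eccentricity * v$axis_ratio, 1, tolerance = 1e-9)
    expect_equal(v$ap_ratio * v$perimeter, v$area, tolerance = 1e-9)
    expect_equal(v$bounding_box,
                 v$major_axis_length * v$minor_axis_length,
                 tolerance = 1e-9)
    expect_equal(v$tep_difference,
                 v$perimeter * (1 - 1 / v$tep_ratio), tolerance = 1e-9)
    expect_equal(v$tcp_difference,
                 v$perimeter * (1 - 1 / v$tcp_ratio), tolerance = 1e-9)
  }
})

test_that("feature selection returns the right subsets in order", {
  fv <- extractFeatures(ellipseContour(60, 30))
  sel <- selectFeatures(fv, "tirads11")
  expect_identical(names(sel), tiradsFeatureNames())
  disc <- selectFeatures(fv, "discounted16")
  expect_length(disc, 16L)
  expect_length(intersect(names(disc), tiradsFeatureNames()), 0L)
  glob <- selectFeatures(fv, "global27")
  expect_identical(names(glob), gmFeatureNames())
  expect_length(selectedColumnNames("tirads11"), 11L)
  expect_length(selectedColumnNames("discounted16"), 17L)
  expect_length(selectedColumnNames("global27"), 28L)
  broken <- fv
  broken@values <- fv@values[-3]
  expect_error(selectFeatures(broken), "incomplete feature vector")
})

test_that("dimensionless features are invariant to exact transforms", {
  base <- contourPoints(randomBlob(11))
  v0 <- flattenFeatures(extractFeatures(NoduleContour(base)))
  dl <- dimensionlessFeatures()
  # translation: exact to tight tolerance
  vt <- flattenFeatures(extractFeatures(NoduleContour(
    sweep(base, 2, c(37.5, -12.25), "+"))))
  expect_equal(vt[dl], v0[dl], tolerance = 1e-8)
  # uniform scaling leaves every ratio unchanged; the boundary-profile
  # variances are computed on equal-arc-length resamples, whose normalized
  # positions are identical under scaling, so they stay exact too
  vs <- flattenFeatures(extractFeatures(NoduleContour(base * 1.7)))
  expect_equal(vs[dl], v0[dl], tolerance = 1e-6)
  # scaling multiplies lengths and areas by the right powers
  expect_equal(unname(vs["area"]), unname(v0["area"]) * 1.7^2,
               tolerance = 1e-9)
  expect_equal(unname(vs["perimeter"]), unname(v0["perimeter"]) * 1.7,
               tolerance = 1e-9)
  expect_equal(unname(vs["major_axis_length"]),
               unname(v0["major_axis_length"]) * 1.7, tolerance = 1e-9)
})

test_that("orientation follows the major axis under exact rotation", {
  v0 <- featureValues(extractFeatures(ellipseContour(60, 30, rotDeg = 0)))
  expect_lt(abs(v0$orientation - 0), 2)
  v30 <- featureValues(extractFeatures(ellipseContour(60, 30, rotDeg = 30)))
  expect_lt(abs(v30$orientation - 30), 2)
  vm60 <- featureValues(extractFeatures(ellipseContour(60, 30,
                                                       rotDeg = -60)))
  expect_lt(abs(vm60$orientation + 60), 2)
})

test_that("reference-shape options propagate into the perimeter ratios", {
  ct <- ellipseContour(60, 30)
  vEq <- featureValues(extractFeatures(ct, tcpReference = "equal_area"))
  vMd <- featureValues(extractFeatures(ct, tcpReference = "major_diameter"))
  # the major-diameter circle is longer than the equal-area circle for an
  # elongated shape, so its tcp_ratio is smaller
  expect_lt(vMd$tcp_ratio, vEq$tcp_ratio)
  vMo <- featureValues(extractFeatures(ct, tepReference = "moments_ellipse"))
  expect_lt(abs(vMo$tep_ratio - 1), 0.05)
})
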