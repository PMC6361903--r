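test_that("discretization matches the floor formula with max-value clamp", {
  expect_equal(as.integer(discretize(c(2.5, 5, 7.5, 10), 2)), c(1L, 1L, 2L, 2L))
  lv <- discretize(rep(4.2, 10), 64)
  expect_equal(as.integer(lv), rep(1L, 10))
  expect_equal(attr(lv, "n_levels"), 1L)
  set.seed(5)
  x <- runif(1000)
  lv <- discretize(x, 64)
  oracle <- pmin(64L, floor((x - min(x)) / (max(x) - min(x)) * 64) + 1L)
  expect_equal(as.integer(lv), as.integer(oracle))
  expect_error(discretize(numeric(0)), "empty")
})

test_that("slice GLCM equals brute-force pair enumeration", {
  # 2x2 slice, full mask
  lv <- matrix(c(1L, 1L, 1L, 2L), 2, 2)
  g <- glcm_slice(lv, 2L)
  expect_equal(sum(g$p), 1)
  expect_equal(g$p, t(g$p))
  expect_equal(g$p, naive_glcm_slice(lv, 2L))
  # random masked slices, all directions
  set.seed(21)
  for (rep in 1:10) {
    m <- matrix(sample(c(1:4, NA), 49, replace = TRUE), 7, 7)
    g <- glcm_slice(m, 4L)
    o <- naive_glcm_slice(m, 4L)
    if (is.null(o)) expect_null(g) else expect_equal(g$p, o)
  }
})

test_that("checkerboard with horizontal pairs only gives p12 = p21 = 0.5", {
  cb <- outer(1:4, 1:4, function(r, c) ((r + c) %% 2) + 1L)
  g <- glcm_slice(cb, 2L, directions = "0")
  expect_equal(g$p, matrix(c(0, 0.5, 0.5, 0), 2, 2))
})

test_that("constant slice collapses to p11 = 1 with zero entropy", {
  g <- glcm_slice(matrix(1L, 3, 3), 1L)
  expect_equal(g$p, matrix(1, 1, 1))
  expect_equal(unname(glcm_features(g)["Entropy"]), 0)
})

test_that("slice with no valid pair is signaled by NULL", {
  lv <- matrix(NA_integer_, 3, 3)
  lv[1, 1] <- 1L; lv[3, 3] <- 2L  # no neighboring in-mask pair
  expect_null(glcm_slice(lv, 2L))
})

test_that("hand-evaluated features of the uniform 2-level matrix", {
  g <- structure(list(p = matrix(0.25, 2, 2), n_levels = 2L), class = "glcm")
  f <- glcm_features(g)
  expect_equal(unname(f["Energy"]), 0.25)
  expect_equal(unname(f["Entropy"]), 2)
  expect_equal(unname(f["Contrast"]), 0.5)
  expect_equal(unname(f["InverseVariance"]), 0.5)
})

test_that("degenerate constant-image limits hold", {
  g <- structure(list(p = matrix(1, 1, 1), n_levels = 1L), class = "glcm")
  f <- glcm_features(g)
  expect_equal(unname(f[c("Contrast", "Entropy", "InverseVariance",
                          "InformationMeasureCorr1",
                          "InformationMeasureCorr2")]),
               rep(0, 5))
  expect_equal(unname(f[c("Energy", "Homogeneity")]), c(1, 1))
})

test_that("every GLCM feature matches the double-loop oracle on random matrices", {
  set.seed(17)
  for (rep in 1:100) {
    g <- random_glcm(sample(2:8, 1))
    f <- glcm_features(g)
    o <- naive_glcm_features(g$p)
    expect_equal(f[names(o)], o, tolerance = 1e-12)
    expect_true(f["InformationMeasureCorr2"] >= 0 &&
                  f["InformationMeasureCorr2"] < 1)
    expect_true(f["Energy"] > 0 && f["Energy"] <= 1)
  }
})

test_that("2.5D aggregation is the unweighted slice mean", {
  a <- stats::setNames(rep(1, 22), petromics::feature_names()[9:30])
  expect_equal(aggregate_2_5d(list(a, a, a)), a)
  b <- a; b["Contrast"] <- 0; c2 <- a; c2["Contrast"] <- 1
  expect_equal(unname(aggregate_2_5d(list(b, c2))["Contrast"]), 0.5)
  set.seed(2)
  m <- matrix(rnorm(5 * 22), 5, 22, dimnames = list(NULL, names(a)))
  expect_equal(aggregate_2_5d(asplit(m, 1)), colMeans(m))
  expect_error(aggregate_2_5d(list()), "too thin")
})

test_that("intensity features: worked example, constants, moment oracle", {
  f <- intensity_features(c(1, 2, 3, 4), 4)
  expect_equal(unname(f["GlobalMax"]), 4)
  expect_equal(unname(f["GlobalMean"]), 2.5)
  expect_equal(unname(f["InterQuartileRange"]),
               unname(quantile(c(1, 2, 3, 4), 0.75) - quantile(c(1, 2, 3, 4), 0.25)))
  fc <- intensity_features(rep(3.3, 20))
  expect_equal(unname(fc[c("GlobalEntropy", "GlobalStdDev", "Skewness",
                           "Kurtosis")]), rep(0, 4))
  expect_equal(unname(fc["GlobalUniformity"]), 1)
  # moment formulas against direct computation on shifted normals
  set.seed(8)
  x <- rnorm(1000) + 10
  f <- intensity_features(x)
  m <- mean(x); m2 <- mean((x - m)^2)
  expect_equal(unname(f["Skewness"]), mean((x - m)^3) / m2^1.5)
  expect_equal(unname(f["Kurtosis"]), mean((x - m)^4) / m2^2 - 3)
  expect_lt(abs(f["Skewness"]), 0.25)
  expect_lt(abs(f["Kurtosis"]), 0.5)
})

test_that("shape features: single voxel, axial pair, all-pairs oracle", {
  v <- suv_volume(array(c(9, rep(0, 26)), c(3, 3, 3)), c(10, 10, 10))
  seg <- threshold_segment(v, site_mask(array(TRUE, c(3, 3, 3))))
  f <- shape_features(seg)
  expect_equal(unname(f), c(0, 1.0, 1))
  # two voxels 30 mm apart along the slice axis
  a <- array(0, c(4, 1, 1)); a[1, 1, 1] <- 9; a[4, 1, 1] <- 9
  v <- suv_volume(a, c(5, 5, 10))
  seg <- threshold_segment(v, site_mask(array(TRUE, c(4, 1, 1))))
  expect_equal(unname(shape_features(seg)["Max3DDiameter"]), 30)
  # random blob vs O(n^2) oracle
  set.seed(13)
  for (rep in 1:3) {
    a <- array(ifelse(runif(6^3) < 0.25, 9, 0), c(6, 6, 6))
    if (sum(a > 0) < 2) next
    v <- suv_volume(a, c(3.9, 3.9, 3.27))
    seg <- threshold_segment(v, site_mask(array(TRUE, c(6, 6, 6))))
    expect_equal(unname(shape_features(seg)["Max3DDiameter"]),
                 naive_max_diameter(seg))
  }
})

test_that("full extraction returns the 33-name schema and honors degeneracy", {
  ph <- generate_phantom(single_lesion_spec(volume_cc = 12, target_suv_max = 8,
                                            texture_sd = 0, seed = 4))
  fv <- extract_feature_vector(ph$vol, ph$mask)
  expect_named(fv, feature_names())
  expect_true(all(is.finite(fv)))
  expect_equal(unname(fv["GlobalMax"]), 8.0)
  # uniform lesion: heterogeneity features at their degenerate values
  expect_equal(unname(fv[c("Contrast", "Entropy", "InverseVariance",
                           "GlobalEntropy", "InformationMeasureCorr2")]),
               rep(0, 5))
  expect_equal(unname(fv[c("Energy", "Homogeneity", "GlobalUniformity")]),
               rep(1, 3))
  # below the volume floor it must refuse
  small <- generate_phantom(single_lesion_spec(volume_cc = 12, seed = 4))
  expect_error(extract_feature_vector(small$vol, small$mask, min_cc = 1e12),
               "below the")
})

test_that("pooled-direction features are invariant to in-plane 90-degree rotation", {
  set.seed(30)
  lv <- matrix(sample(1:5, 36, replace = TRUE), 6, 6)
  f1 <- glcm_features(glcm_slice(lv, 5L))
  rot <- t(lv[nrow(lv):1, ])  # 90-degree rotation
  f2 <- glcm_features(glcm_slice(rot, 5L))
  expect_equal(f1, f2, tolerance = 1e-12)
})

test_that("features are invariant to voxel traversal order (set semantics)", {
  ph <- generate_phantom(single_lesion_spec(volume_cc = 15, texture_sd = 0.8,
                                            seed = 6))
  f1 <- extract_feature_vector(ph$vol, ph$mask)
  f2 <- extract_feature_vector(ph$vol, ph$mask)  # identical inputs, rebuilt
  expect_identical(f1, f2)
})
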