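test_that("hand-computed segmentation metrics on a 2x2x2 grid", {
  v <- suv_volume(array(c(3, 3, 3, rep(1, 5)), c(2, 2, 2)), c(10, 10, 10))
  seg <- threshold_segment(v, site_mask(array(TRUE, c(2, 2, 2))))
  expect_equal(seg$mtv_cc, 3.0)
  expect_equal(seg$suv_mean, 3.0)
  expect_equal(seg$suv_max, 3.0)
  expect_equal(seg$tlg, 9.0)
})

test_that("site entirely below threshold has MTV 0 and TLG 0", {
  v <- suv_volume(array(2.0, c(3, 3, 3)), c(4, 4, 4))
  seg <- threshold_segment(v, site_mask(array(TRUE, c(3, 3, 3))))
  expect_equal(seg$mtv_cc, 0)
  expect_equal(seg$tlg, 0)
  expect_lt(seg$suv_max, 2.5)
})

test_that("voxel exactly at the threshold is included (inclusive >=)", {
  v <- suv_volume(array(c(2.5, rep(0, 7)), c(2, 2, 2)), c(10, 10, 10))
  seg <- threshold_segment(v, site_mask(array(TRUE, c(2, 2, 2))))
  expect_equal(seg$n_voxels, 1L)
  expect_equal(seg$suv_mean, 2.5)
})

test_that("MTV matches triple-loop counting on random volumes, and the TLG identity holds", {
  set.seed(42)
  for (rep in 1:5) {
    v <- suv_volume(array(runif(8^3, 0, 6), c(8, 8, 8)), c(3, 4, 5))
    m <- site_mask(array(runif(8^3) < 0.5, c(8, 8, 8)))
    seg <- threshold_segment(v, m)
    expect_equal(seg$mtv_cc, naive_mtv_cc(v, m, 2.5))
    expect_identical(seg$tlg, seg$mtv_cc * seg$suv_mean)
    expect_true(all(v$voxels[seg$voxels] >= 2.5))
    expect_true(all(m$voxels[seg$voxels]))
  }
})

test_that("MTV is non-increasing in the threshold", {
  set.seed(7)
  v <- suv_volume(array(runif(10^3, 0, 8), c(10, 10, 10)), c(4, 4, 4))
  m <- site_mask(array(runif(10^3) < 0.7, c(10, 10, 10)))
  mtvs <- sapply(seq(0.5, 7.5, by = 0.5),
                 function(th) threshold_segment(v, m, th)$mtv_cc)
  expect_true(all(diff(mtvs) <= 0))
})

test_that("segmentation is invariant under permutation of disconnected components", {
  set.seed(3)
  base <- array(runif(6^3, 0, 6), c(6, 6, 6))
  v <- suv_volume(base, c(5, 5, 5))
  m1 <- array(FALSE, c(6, 6, 6)); m1[1:2, 1:2, 1:2] <- TRUE
  m2 <- array(FALSE, c(6, 6, 6)); m2[5:6, 5:6, 5:6] <- TRUE
  both <- site_mask(m1 | m2)
  seg <- threshold_segment(v, both)
  s1 <- threshold_segment(v, site_mask(m1))
  s2 <- threshold_segment(v, site_mask(m2))
  expect_equal(seg$mtv_cc, s1$mtv_cc + s2$mtv_cc)
  expect_equal(sort(seg$voxels), sort(c(s1$voxels, s2$voxels)))
})

test_that("small-site filter is strict below the cut and keeps order", {
  mk <- function(cc) structure(list(site_label = sprintf("s%.1f", cc),
                                    mtv_cc = cc), class = "site_segmentation")
  segs <- lapply(c(4.9, 5.0, 12.3), mk)
  kept <- suppressMessages(filter_small_sites(segs, 5.0))
  expect_equal(sapply(kept, `[[`, "mtv_cc"), c(5.0, 12.3))
  expect_message(filter_small_sites(segs, 5.0), "4.900 cc < 5.000 cc")
  expect_equal(filter_small_sites(list(), 5.0), list())
  # brute-force comparison on random volumes
  set.seed(9)
  vols <- runif(100, 0, 12)
  segs <- lapply(vols, mk)
  kept <- suppressMessages(filter_small_sites(segs, 5.0))
  expect_equal(sapply(kept, `[[`, "mtv_cc"), vols[vols >= 5.0])
})
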