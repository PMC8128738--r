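full_mask <- function(vol) array(TRUE, dim(vol$voxels))

test_that("density weights follow the four classic HU bins", {
  expect_identical(density_weight(c(130, 199, 200, 299, 300, 399, 400, 5000)),
                   c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L))
  expect_error(density_weight(129.9), "130")
})

test_that("calcium mask is the region intersected with an inclusive threshold", {
  vol <- ct_volume(array(-50, c(8, 8, 3)))
  expect_equal(sum(calcium_mask(vol, full_mask(vol), 130)), 0)
  v2 <- ct_volume(array(-50, c(8, 8, 3)))
  v2$voxels[3, 4, 2] <- 130
  expect_equal(which(calcium_mask(v2, full_mask(v2), 130)),
               which(v2$voxels == 130))
  expect_error(calcium_mask(vol, full_mask(vol), 100), ">= 130")
  # random volume equals the per-voxel brute-force test
  set.seed(2)
  v3 <- ct_volume(array(rnorm(8 * 8 * 3, 100, 80), c(8, 8, 3)))
  region <- array(runif(8 * 8 * 3) < 0.5, c(8, 8, 3))
  got <- calcium_mask(v3, region, 130)
  for (i in seq_along(got))
    expect_equal(got[i], region[i] && v3$voxels[i] >= 130)
})

test_that("lesion extraction uses per-slice 8-connectivity and an area floor", {
  vol <- ct_volume(array(0, c(6, 6, 2)), pixel_spacing = 0.5)
  vol$voxels[2, 2, 1] <- 200
  vol$voxels[3, 3, 1] <- 300  # diagonal contact: one lesion
  les <- extract_lesions(calcium_mask(vol, full_mask(vol)), vol, min_area = 0)
  expect_length(les, 1)
  expect_equal(les[[1]]$n_pixels, 2)
  expect_equal(les[[1]]$max_hu, 300)
  expect_equal(les[[1]]$weight, 3L)
  # a single 0.25 mm2 pixel is dropped at the default 1 mm2 floor
  expect_length(extract_lesions(calcium_mask(vol, full_mask(vol)), vol,
                                min_area = 1), 0)
  # same pixels on different slices stay separate lesions
  vol$voxels[2, 2, 2] <- 200
  les2 <- extract_lesions(calcium_mask(vol, full_mask(vol)), vol,
                          min_area = 0)
  expect_length(les2, 2)
  expect_equal(sort(vapply(les2, `[[`, integer(1), "slice_index")), 1:2)
})

test_that("lesion scores scale with area, weight and slice thickness", {
  # 10 pixels of 0.5 x 0.5 mm at 350 HU on a 3 mm slice: 2.5 mm2 x 3 x 1 = 7.5
  vol <- ct_volume(array(0, c(8, 8, 1)), pixel_spacing = 0.5,
                   slice_thickness = 3)
  vol$voxels[2:6, 2, 1] <- 340
  vol$voxels[2:6, 3, 1] <- 350
  les <- extract_lesions(calcium_mask(vol, full_mask(vol)), vol)
  expect_length(les, 1)
  expect_equal(les[[1]]$area_mm2, 2.5)
  expect_equal(les[[1]]$score, 7.5)
  expect_equal(lesion_score(les[[1]], 3), 7.5)
  # the same in-plane lesion on two 1.5 mm slices totals the same 7.5
  vol2 <- ct_volume(array(0, c(8, 8, 2)), pixel_spacing = 0.5,
                    slice_thickness = 1.5)
  vol2$voxels[2:6, 2:3, 1:2] <- 350
  les2 <- extract_lesions(calcium_mask(vol2, full_mask(vol2)), vol2)
  expect_length(les2, 2)
  expect_equal(sum(vapply(les2, `[[`, numeric(1), "score")), 7.5)
})

test_that("artery scores are additive over separated lesions", {
  vol <- ct_volume(array(0, c(40, 40, 9)))
  vol$voxels[10:12, 10:12, 4:6] <- 250
  vol$voxels[28:30, 28:30, 4:6] <- 450
  near <- scoring_region("CA", c(10, 10, 4), 5)
  far <- scoring_region("SMA", c(28, 28, 4), 5)
  both <- scoring_region("IMA", c(19, 19, 4), 18)
  s_near <- artery_macs(vol, near)$macs
  s_far <- artery_macs(vol, far)$macs
  s_both <- artery_macs(vol, both)$macs
  expect_gt(s_near, 0)
  expect_gt(s_far, 0)
  expect_equal(s_both, s_near + s_far)
})

test_that("raising HU never lowers the score; shrinking the region never raises it", {
  set.seed(31)
  for (rep in 1:5) {
    vox <- array(rnorm(16 * 16 * 4, 60, 90), c(16, 16, 4))
    vol <- ct_volume(vox)
    region <- scoring_region("CA", c(7, 7, 1.5), 6)
    base <- artery_macs(vol, region)$macs
    # raise a handful of voxels inside the territory
    vol2 <- vol
    idx <- which(scoring_mask(region, vol))[c(3, 17, 40)]
    vol2$voxels[idx] <- vol2$voxels[idx] + 300
    expect_gte(artery_macs(vol2, region)$macs, base)
    smaller <- scoring_region("CA", c(7, 7, 1.5), 3)
    expect_lte(artery_macs(vol, smaller)$macs, base)
  }
})

test_that("the scorer matches the brute-force oracle on small volumes", {
  set.seed(17)
  for (rep in 1:3) {
    vox <- array(rnorm(12 * 12 * 3, 40, 110), c(12, 12, 3))
    vol <- ct_volume(vox, pixel_spacing = 0.8, slice_thickness = 2)
    region <- scoring_region("CA", c(4.8, 4.8, 2), 4)
    mask <- scoring_mask(region, vol)
    expect_equal(artery_macs(vol, region)$macs,
                 oracle_macs(vox, mask, c(0.8, 0.8), 2),
                 tolerance = 1e-12)
  }
})

test_that("profiles sum the three arteries and reject duplicate labels", {
  mk <- function(artery, macs) structure(list(artery = artery, macs = macs),
                                         class = "artery_score")
  p <- macs_profile(mk("CA", 100), mk("SMA", 200), mk("IMA", 30))
  expect_equal(p$ca_plus_sma, 300)
  expect_equal(p$total, 330)
  p0 <- macs_profile(mk("CA", 0), mk("SMA", 0), mk("IMA", 0))
  expect_equal(p0$total, 0)
  expect_error(macs_profile(mk("CA", 1), mk("CA", 2), mk("IMA", 3)),
               "duplicate|order")
  set.seed(5)
  for (rep in 1:10) {
    v <- runif(3, 0, 2000)
    p <- macs_profile(mk("CA", v[1]), mk("SMA", v[2]), mk("IMA", v[3]))
    expect_equal(p$ca_plus_sma, v[1] + v[2])
    expect_equal(p$total, sum(v))
  }
})

test_that("contrast density is mean + 2 x sample sd of the aortic ROI", {
  vol <- ct_volume(array(300, c(6, 6, 2)))
  cd <- contrast_density(vol, list(center_mm = c(2, 2), radius_mm = 1.5,
                                   slice_index = 1))
  expect_equal(cd$density, 300)  # sd 0 on a uniform lumen
  v2 <- ct_volume(array(rep(c(590, 610), 8), c(4, 4, 1)))
  roi <- array(FALSE, c(4, 4, 1)); roi[1:2, 1, 1] <- TRUE
  cd2 <- contrast_density(v2, roi)
  expect_equal(cd2$mean_hu, 600)
  expect_equal(cd2$density, 600 + 2 * sqrt(200), tolerance = 1e-12)  # 628.28
  set.seed(9)
  for (rep in 1:5) {
    v3 <- ct_volume(array(rnorm(27, 400, 60), c(3, 3, 3)))
    cd3 <- contrast_density(v3, array(TRUE, c(3, 3, 3)))
    expect_gte(cd3$density, cd3$mean_hu)
  }
  one <- array(FALSE, c(4, 4, 1)); one[1, 1, 1] <- TRUE
  expect_error(contrast_density(v2, one), "at least 2")
})

test_that("adaptive thresholding raises the threshold to the contrast density", {
  set.seed(12)
  vox <- array(40, c(40, 40, 9))
  vox[15:25, 15:25, ] <- rnorm(11 * 11 * 9, 300, 20)  # noisy contrast lumen
  vox[8:9, 19:20, 5] <- 600            # true calcium, above the enhancement
  vol <- ct_volume(vox)
  roi <- list(center_mm = c(19, 19), radius_mm = 3, slice_index = 5)
  region <- scoring_region("CA", c(14, 19, 4), 8, aorta_roi = roi)
  plain <- artery_macs(vol, region)
  suppressMessages(adaptive <- artery_macs(vol, region,
                                           adaptive_threshold = TRUE))
  expect_gt(adaptive$threshold_used, 300)   # mean + 2 sd of the lumen
  expect_lt(adaptive$macs, 0.25 * plain$macs)  # lumen leakage suppressed
  expect_gt(adaptive$macs, 0)               # the true lesion survives
  expect_true(all(vapply(adaptive$lesions, `[[`, numeric(1), "max_hu") >=
                    adaptive$threshold_used))
})
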