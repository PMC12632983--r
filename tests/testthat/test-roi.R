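make_prob <- function(values, voxel = 2) {
  structure(list(values = values, voxel_size_mm = rep(voxel, 3),
                 fwhm_mm = 10), class = "prob_volume")
}

test_that("threshold_to_volume hits the target count", {
  set.seed(21)
  v <- array(stats::runif(30^3), c(30, 30, 30))      # distinct values
  pm <- make_prob(v)
  m <- threshold_to_volume(pm, 10)                   # 0.008 mL/voxel
  expect_equal(sum(m$mask), 1250)
  expect_equal(m$volume_mL, 10)
  # mask equals {map >= threshold} when boundary values are distinct
  expect_equal(m$mask, v >= m$threshold_used)
})

test_that("threshold edge cases: full support, ties, unattainable", {
  v <- array(0, c(10, 10, 10)); v[1:500] <- seq(0.5, 1, length.out = 500)
  pm <- make_prob(v)
  full <- threshold_to_volume(pm, 500 * 0.008)
  expect_equal(sum(full$mask), 500)
  expect_equal(full$threshold_used, 0.5)             # smallest positive value
  cst <- make_prob(array(1, c(10, 10, 10)))
  m1 <- threshold_to_volume(cst, 1)                  # 125 of 1000 equal voxels
  expect_equal(sum(m1$mask), 125)
  expect_equal(which(as.vector(m1$mask)), 1:125)     # lexicographic ties
  expect_error(threshold_to_volume(pm, 100), "unattainable.*at most 4")
})

test_that("FBWM series volumes are exact and strictly nested", {
  fb <- default_fbwm()
  sizes <- c(0.5, 1, 2, 5, 10, 20, 45, 100, 200)
  expect_equal(length(fb), 9)
  vox <- voxel_volume_mL(2)
  for (i in seq_along(fb)) {
    expect_lte(abs(fb[[i]]$volume_mL - sizes[i]), vox)
  }
  for (i in seq_len(length(fb) - 1)) {
    expect_true(all(fb[[i + 1]]$mask[fb[[i]]$mask]))   # nesting
    expect_lt(fb[[i]]$volume_mL, fb[[i + 1]]$volume_mL)
    expect_gte(fb[[i]]$threshold_used, fb[[i + 1]]$threshold_used)
  }
  expect_error(make_fbwm_series(default_labels(), sizes_mL = c(5, 2)))
  one <- make_fbwm_series(default_labels(), sizes_mL = 10)
  expect_identical(one$FBWM_10mL$mask, fb$FBWM_10mL$mask)
})

test_that("WM map is a probability map; point source reproduces the kernel", {
  lab <- small_labels()
  wm <- make_wm_map(lab, "cerebral_wm", 10)
  expect_gte(min(wm$values), 0)
  expect_lte(max(wm$values), 1)
  expect_error(make_wm_map(lab, "nope"), "unknown region")
  # single-voxel source: peak equals the central 3-D kernel weight
  arr <- array(0L, c(21, 21, 21)); arr[11, 11, 11] <- 2L
  lv <- label_volume(arr, 2, c(cerebral_wm = 2L))
  mp <- make_wm_map(lv, "cerebral_wm", 10)
  k <- gaussian_kernel_1d(10 / (2 * sqrt(2 * log(2))) / 2)
  central <- k[(length(k) + 1) / 2]^3
  expect_equal(mp$values[11, 11, 11], central, tolerance = 1e-12)
})

test_that("merging GM labels yields 12 disjoint masks with additive volume", {
  lab <- default_labels()
  gm <- default_gm_rois()
  expect_equal(length(gm), 12)
  expect_setequal(names(gm), GM_REGIONS)
  tot <- Reduce(`+`, lapply(gm, function(m) m$mask * 1L))
  expect_lte(max(tot), 1)                            # disjoint
  two <- merge_gm_rois(lab, list(both = c(lab$code_map[["frontal"]],
                                          lab$code_map[["parietal"]])))
  expect_equal(two$both$volume_mL,
               gm$frontal$volume_mL + gm$parietal$volume_mL)
  expect_error(merge_gm_rois(lab, list(x = 999L)), "unknown code")
  expect_error(merge_gm_rois(lab, list(x = integer(0))), "empty merge")
})

test_that("TAC extraction averages in-mask voxels per frame", {
  sch <- frame_schedule(c(0, 1), c(1, 2))
  dat <- array(0, c(3, 3, 3, 2))
  dat[1, 1, 1, ] <- c(2, 4); dat[2, 1, 1, ] <- c(6, 8)
  img <- dynamic_image(dat, sch, 2)
  m <- array(FALSE, c(3, 3, 3)); m[1:2, 1, 1] <- TRUE
  roi <- roi_mask(m, "two", 2)
  expect_equal(extract_tac(img, roi)$values, c(4, 6))
  single <- array(FALSE, c(3, 3, 3)); single[2, 1, 1] <- TRUE
  expect_equal(extract_tac(img, roi_mask(single, "one", 2))$values, c(6, 8))
  uni <- dynamic_image(array(7, c(3, 3, 3, 2)), sch, 2)
  expect_equal(extract_tac(uni, roi)$values, c(7, 7))
  bad <- roi_mask(array(TRUE, c(4, 4, 4)), "bad", 2)
  expect_error(extract_tac(img, bad), "grids differ")
})
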