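test_that("without PSF and noise every voxel carries its region TAC", {
  lab <- small_labels(); tr <- default_truth()
  cp <- default_cp(); sch <- default_sched()
  img <- simulate_dynamic_pet(lab, tr, cp, sch, psf_fwhm_mm = 0, noise_scale = 0)
  wm_tac <- onetcm_predict(tr$K1[["cerebral_wm"]], tr$k2[["cerebral_wm"]],
                           cp, sch)$values
  wmvox <- which(lab$labels == lab$code_map[["cerebral_wm"]], arr.ind = TRUE)[1, ]
  expect_equal(img$data[wmvox[1], wmvox[2], wmvox[3], ], wm_tac)
  bg <- which(lab$labels == 0L, arr.ind = TRUE)[1, ]
  expect_equal(img$data[bg[1], bg[2], bg[3], ], rep(0, 21))
})

test_that("simulation is bit-reproducible given the seed", {
  lab <- small_labels(); tr <- default_truth()
  cp <- default_cp(); sch <- default_sched()
  i1 <- simulate_dynamic_pet(lab, tr, cp, sch, 6, 10, seed = 99)
  i2 <- simulate_dynamic_pet(lab, tr, cp, sch, 6, 10, seed = 99)
  expect_identical(i1$data, i2$data)
  i3 <- simulate_dynamic_pet(lab, tr, cp, sch, 6, 10, seed = 100)
  expect_false(identical(i1$data, i3$data))
})

test_that("PSF conserves total activity and injects spill-in near GM", {
  lab <- small_labels(); tr <- default_truth()
  cp <- default_cp(); sch <- default_sched()
  sharp <- simulate_dynamic_pet(lab, tr, cp, sch, 0, 0)
  blur <- simulate_dynamic_pet(lab, tr, cp, sch, 6, 0)
  s0 <- apply(sharp$data, 4, sum); s1 <- apply(blur$data, 4, sum)
  expect_lt(max(abs(s1 / s0 - 1)), 5e-3)
  # a WM voxel near cortex re-fits above WM truth; near the reference
  # pocket it stays close (monotone spill-in with distance from GM)
  spec <- small_spec()
  near <- round(c(0, 0, spec$wm_semiaxes_mm[3] - 3) /
                  spec$voxel_size_mm + (spec$grid_shape + 1) / 2)
  deep <- round(spec$cs_center_mm / spec$voxel_size_mm +
                  (spec$grid_shape + 1) / 2)
  expect_equal(lab$labels[near[1], near[2], near[3]],
               lab$code_map[["cerebral_wm"]])
  fit_vox <- function(ix) {
    fit_onetcm(tac(sch, blur$data[ix[1], ix[2], ix[3], ]), cp)$VT
  }
  vt_near <- fit_vox(near); vt_deep <- fit_vox(deep)
  expect_gt(vt_near, tr$VT[["cerebral_wm"]] * 1.05)
  expect_gt(vt_near, vt_deep)
  expect_equal(vt_deep, tr$VT[["cerebral_wm"]], tolerance = 0.02)
})

test_that("regions missing from the kinetic truth are reported", {
  lab <- small_labels()
  tr <- default_truth()
  tr$K1 <- tr$K1[setdiff(names(tr$K1), "amygdala")]
  expect_error(
    simulate_dynamic_pet(lab, tr, default_cp(), default_sched()),
    "missing from kinetic truth: amygdala")
})

test_that("cohort streams are stable when subjects are added", {
  spec <- small_spec(); tr <- default_truth()
  c1 <- simulate_cohort(spec, tr, cohort_spec(n_HS = 3, n_PD = 2,
                                              n_same_day = 1, seed = 5))
  c2 <- simulate_cohort(spec, tr, cohort_spec(n_HS = 5, n_PD = 3,
                                              n_same_day = 1, seed = 5))
  expect_identical(c1$scan_truths[[1]]$K1, c2$scan_truths[[1]]$K1)
  expect_identical(c1$scan_truths[[6]]$K1, c2$scan_truths[[6]]$K1)
  expect_equal(c1$scans$interscan_days[1:6], c2$scans$interscan_days[1:6])
})

test_that("cohort design matches the requested structure", {
  spec <- small_spec(); tr <- default_truth()
  co <- simulate_cohort(spec, tr,
                        cohort_spec(n_HS = 9, n_PD = 4, n_same_day = 3, seed = 2))
  sc <- co$scans
  expect_equal(sum(sc$group == "HS"), 18)          # two scans per pair
  expect_equal(sum(sc$group == "PD"), 4)
  expect_equal(sum(sc$pair_type == "same_day"), 6)
  expect_true(all(sc$interscan_days[sc$pair_type == "same_day"] == 0))
  lng <- sc$interscan_days[sc$pair_type == "longitudinal"]
  expect_true(all(lng >= 7 & lng <= 1028))
  # PD effect applies to SN/caudate/brainstem only, on average (1 - effect)
  co0 <- simulate_cohort(spec, tr,
                         cohort_spec(n_HS = 2, n_PD = 6, pd_effect = 0.2,
                                     between_subject_cv = 0,
                                     within_subject_cv = 0,
                                     subject_scale_cv = 0, scan_scale_cv = 0,
                                     seed = 3))
  pd_idx <- which(co0$scans$group == "PD")
  for (i in pd_idx) {
    expect_equal(co0$scan_truths[[i]]$VT[["substantia_nigra"]],
                 tr$VT[["substantia_nigra"]] * 0.8)
    expect_equal(co0$scan_truths[[i]]$VT[["frontal"]], tr$VT[["frontal"]])
  }
})

test_that("ROI shortcut equals the image path exactly when noise-free", {
  lab <- small_labels(); spec <- small_spec(); tr <- default_truth()
  rois <- list(cs = cs_analogue_mask(lab, spec),
               frontal = region_mask(lab, "frontal"))
  ct <- roi_crosstalk(lab, rois, psf_fwhm_mm = 6)
  short <- simulate_roi_tacs(ct, tr, default_cp(), default_sched(),
                             noise_scale = 0)
  img <- simulate_dynamic_pet(lab, tr, default_cp(), default_sched(), 6, 0)
  for (nm in names(rois)) {
    expect_equal(short[[nm]]$values, extract_tac(img, rois[[nm]])$values,
                 tolerance = 1e-12)
  }
})

test_that("ROI shortcut noise matches the voxel-level noise variance", {
  lab <- small_labels(); spec <- small_spec(); tr <- default_truth()
  rois <- list(cs = cs_analogue_mask(lab, spec))
  ct <- roi_crosstalk(lab, rois, psf_fwhm_mm = 0)
  sch <- frame_schedule(0, 5)
  cpd <- default_cp()
  base <- unname(simulate_roi_tacs(ct, tr, cpd, sch, noise_scale = 0)$cs$values)
  # analytic ROI-mean SD: ns * sqrt(mean C / dt) / sqrt(n)
  want_sd <- 10 * sqrt(base / 5) / sqrt(ct$n_vox[["cs"]])
  set.seed(31)
  draws <- replicate(300, {
    s <- sample.int(1e6, 1)
    img <- simulate_dynamic_pet(lab, tr, cpd, sch, 0, 10, seed = s)
    extract_tac(img, rois$cs)$values
  })
  expect_equal(stats::sd(draws), want_sd, tolerance = 0.12)
  expect_equal(mean(draws), base, tolerance = 0.02)
})

test_that("zero-variance test-retest cohorts give identically zero TRV", {
  spec <- small_spec(); tr <- default_truth()
  lab <- small_labels()
  co <- simulate_cohort(spec, tr,
                        cohort_spec(n_HS = 3, n_PD = 2, noise_scale = 0,
                                    between_subject_cv = 0.05,
                                    within_subject_cv = 0,
                                    subject_scale_cv = 0, scan_scale_cv = 0,
                                    seed = 8))
  rois <- list(frontal = region_mask(lab, "frontal"),
               cs = cs_analogue_mask(lab, spec))
  scans <- cohort_roi_tacs(co, rois, method = "roi", labels = lab)
  scans <- Filter(function(s) s$group == "HS", scans)
  vt <- compute_vt_table(scans)
  tr_rec <- trv_records(vt, measure = "VT")
  expect_lt(max(abs(tr_rec$trv_percent)), 1e-3)
})

test_that("with kinetics off, a PD effect moves DVR by the injected fraction", {
  spec <- small_spec(); tr <- default_truth(); lab <- small_labels()
  co <- simulate_cohort(spec, tr,
                        cohort_spec(n_HS = 2, n_PD = 2, pd_effect = 0.10,
                                    noise_scale = 0, psf_fwhm_mm = 0,
                                    between_subject_cv = 0,
                                    within_subject_cv = 0,
                                    subject_scale_cv = 0, scan_scale_cv = 0,
                                    seed = 9))
  rois <- list(substantia_nigra = region_mask(lab, "substantia_nigra"),
               cs = cs_analogue_mask(lab, spec))
  scans <- cohort_roi_tacs(co, rois, method = "roi", labels = lab)
  scans <- Filter(function(s) s$scan == 1, scans)
  vt <- compute_vt_table(scans)
  dvr <- compute_dvr(vt, "cs", targets = "substantia_nigra")
  hs <- mean(dvr$dvr[dvr$group == "HS"])
  pd <- mean(dvr$dvr[dvr$group == "PD"])
  expect_equal(100 * (hs - pd) / hs, 10, tolerance = 0.05)
})
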