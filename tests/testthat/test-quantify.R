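test_that("TRV formula: value, zero at equality, antisymmetry, bounds", {
  expect_equal(compute_trv(4, 4), 0)
  expect_equal(compute_trv(4, 4.4), 200 * 0.4 / 8.4)   # +9.5238%
  expect_error(compute_trv(1, -1), "test \\+ retest = 0")
  set.seed(41)
  a <- stats::runif(500, 0.01, 50)
  b <- stats::runif(500, 0.01, 50)
  expect_equal(compute_trv(a, b), -compute_trv(b, a))
  v <- compute_trv(a, b)
  expect_true(all(v > -200 & v < 200))
})

test_that("DVR records: arithmetic, exclusions, calibration invariance", {
  vt <- data.frame(subject = rep(c("s1", "s2"), each = 3),
                   scan = 1,
                   group = "HS", pair_type = "single", interscan_days = NA,
                   region = rep(c("tgt", "tgt2", "ref"), 2),
                   K1 = 0.3, k2 = 0.05,
                   VT = c(10, 5, 4, 8, 6, 2),
                   wrss = 0, converged = TRUE)
  dvr <- compute_dvr(vt, "ref")
  expect_equal(nrow(dvr), 4)
  expect_false("ref" %in% dvr$target)
  expect_equal(dvr$dvr[dvr$subject == "s1" & dvr$target == "tgt"], 2.5)
  # global multiplicative calibration of a scan cancels
  vt2 <- vt; vt2$VT <- vt2$VT * 1.7
  expect_equal(compute_dvr(vt2, "ref")$dvr, dvr$dvr)
  # failed reference drops the whole scan, with a log message
  vt3 <- vt; vt3$converged[vt3$subject == "s2" & vt3$region == "ref"] <- FALSE
  expect_message(d3 <- compute_dvr(vt3, "ref"), "excluding 1 scan")
  expect_equal(unique(d3$subject), "s1")
  # failed target drops only that region
  vt4 <- vt; vt4$VT[vt4$subject == "s1" & vt4$region == "tgt"] <- NA
  vt4$converged[vt4$subject == "s1" & vt4$region == "tgt"] <- FALSE
  d4 <- compute_dvr(vt4, "ref")
  expect_equal(nrow(d4), 3)
})

test_that("TRV summaries use n-1 SDs and omit singleton cells", {
  rec <- data.frame(subject = c("a", "b", "c"),
                    region = c("r1", "r1", "r2"),
                    measure = "VT", test = 1, retest = 1,
                    trv_percent = c(5, -5, 3),
                    pair_type = "same_day", interscan_days = 0)
  expect_warning(sm <- summarize_trv(rec), "fewer than 2")
  expect_equal(nrow(sm), 1)
  expect_equal(sm$mean_trv, 0)
  expect_equal(sm$sd_trv, sqrt(50))                   # 7.071
})

test_that("GM averaging is within-subject first, not pooled", {
  rec <- expand.grid(subject = c("a", "b", "c"), region = GM_REGIONS[1:3],
                     stringsAsFactors = FALSE)
  rec$measure <- "DVR_x"; rec$pair_type <- "longitudinal"
  rec$interscan_days <- 100; rec$test <- 1; rec$retest <- 1
  set.seed(42)
  rec$trv_percent <- stats::rnorm(nrow(rec), 0, 8)
  ga <- gm_average_trv(rec, gm_regions = GM_REGIONS[1:3])
  # oracle: average regions within subject, then summarize over subjects
  per <- as.numeric(tapply(rec$trv_percent, rec$subject, mean))
  expect_equal(sort(ga$per_subject$gm_trv), sort(per))
  expect_equal(ga$summary$mean_trv, mean(per))
  expect_equal(ga$summary$sd_trv, stats::sd(per))
  # pooling all records first gives a different SD
  expect_false(isTRUE(all.equal(stats::sd(rec$trv_percent), stats::sd(per))))
})

test_that("percent CoV: arithmetic, scale invariance, guards", {
  expect_equal(percent_cov(c(4, 4, 4)), 0)
  expect_equal(percent_cov(c(3, 5)), 100 * sqrt(2) / 4)  # 35.355%
  x <- c(2, 3, 7, 5)
  expect_equal(percent_cov(x * 13), percent_cov(x))
  expect_error(percent_cov(c(-1, 1)), "zero mean")
  expect_error(percent_cov(4))
})

test_that("trv_records pairs test and retest scans by subject and region", {
  vt <- data.frame(subject = c("s1", "s1", "s2", "s2"),
                   scan = c(1, 2, 1, 2),
                   group = "HS",
                   pair_type = "same_day",
                   interscan_days = 0,
                   region = "r1",
                   VT = c(4, 4.4, 5, 5),
                   converged = TRUE)
  rec <- trv_records(vt, measure = "VT")
  expect_equal(nrow(rec), 2)
  expect_equal(rec$trv_percent[rec$subject == "s1"], 200 * 0.4 / 8.4)
  expect_equal(rec$trv_percent[rec$subject == "s2"], 0)
})
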