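# from-scratch oracle for the pooled two-sample comparison
t_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  list(t = t, p = 2 * stats::pt(-abs(t), df),
       d = (mean(a) - mean(b)) / sqrt(sp2))
}

test_that("group comparison matches the definitional formulas", {
  a <- c(5.0, 5.2, 4.8, 5.1); b <- c(4.5, 4.4, 4.7)
  g <- group_compare(a, b)
  o <- t_oracle(a, b)
  expect_equal(g$t, o$t, tolerance = 1e-10)
  expect_equal(g$p, o$p, tolerance = 1e-8)
  expect_equal(g$cohens_d, o$d, tolerance = 1e-10)
  expect_equal(g$pct_diff, 100 * (mean(a) - mean(b)) / mean(a))
  expect_equal(g$pct_sd_A, 100 * stats::sd(a) / mean(a))
})

test_that("group comparison on 100 random group pairs matches the oracle", {
  set.seed(52)
  for (i in 1:100) {
    a <- stats::rnorm(sample(3:9, 1), 10, 2)
    b <- stats::rnorm(sample(3:9, 1), 9, 3)
    g <- group_compare(a, b)
    o <- t_oracle(a, b)
    expect_equal(g$t, o$t, tolerance = 1e-10)
    expect_equal(g$p, o$p, tolerance = 1e-8)
    expect_equal(g$cohens_d, o$d, tolerance = 1e-10)
  }
})

test_that("group comparison edge cases and Welch flag", {
  g0 <- group_compare(c(1, 2, 3), c(1, 2, 3))
  expect_equal(g0$cohens_d, 0)
  expect_equal(g0$p, 1)
  expect_equal(g0$pct_diff, 0)
  g1 <- group_compare(c(1, 2, 3), c(2, 3, 4))
  expect_equal(g1$cohens_d, -1)                    # pooled SD is 1
  gd <- group_compare(c(2, 2), c(2, 2))
  expect_true(gd$degenerate)
  expect_true(is.na(gd$cohens_d))
  a <- c(1, 2, 3, 4); b <- c(0, 5, 10, 30)
  gw <- group_compare(a, b, welch = TRUE)
  gs <- group_compare(a, b, welch = FALSE)
  expect_false(isTRUE(all.equal(gw$p, gs$p)))
  expect_equal(gw$p, stats::t.test(a, b)$p.value)
})

test_that("interscan regression matches the closed-form OLS solution", {
  x <- c(10, 100, 400, 900); y <- c(1, -2, 3, -1)
  r <- interscan_regression(y, x)
  # normal equations
  bx <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  b0 <- mean(y) - bx * mean(x)
  res <- y - b0 - bx * x
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  tstat <- bx / sqrt(sum(res^2) / 2 / sum((x - mean(x))^2))
  expect_equal(r$slope, bx, tolerance = 1e-12)
  expect_equal(r$intercept, b0, tolerance = 1e-12)
  expect_equal(r$rss, sum(res^2), tolerance = 1e-12)
  expect_equal(r$r_squared, r2, tolerance = 1e-12)
  expect_equal(r$p_value, 2 * stats::pt(-abs(tstat), 2), tolerance = 1e-12)
})

test_that("regression degenerate cases", {
  x <- c(1, 2, 3, 4)
  # summary.lm warns on an exactly collinear fit; the values are still exact
  exact <- suppressWarnings(interscan_regression(2 * x + 1, x))
  expect_equal(exact$r_squared, 1)
  expect_equal(exact$rss, 0, tolerance = 1e-20)
  flat <- suppressWarnings(interscan_regression(rep(3, 4), x))
  expect_equal(flat$slope, 0)
  expect_equal(flat$r_squared, 0)
  expect_error(interscan_regression(c(1, 2), c(1, 2)), "at least 3 pairs")
})

test_that("reference bias table flags the <10% criterion strictly", {
  mk <- function(region, vts) {
    data.frame(subject = paste0("s", seq_along(vts)), scan = 1,
               group = "HS", pair_type = "x", interscan_days = NA,
               region = region, K1 = 1, k2 = 1, VT = vts, wrss = 0,
               converged = TRUE)
  }
  vt <- rbind(mk("std", c(4, 4, 4)),
              mk("same", c(4, 4, 4)),
              mk("ten", c(4.4, 4.4, 4.4)),      # exactly +10%: must fail
              mk("nine", c(4.36, 4.36, 4.36)))
  bias <- reference_bias_table(vt, c("same", "ten", "nine"), "std")
  expect_equal(bias$pct_diff[bias$reference == "std"], 0)
  expect_true(bias$passes_bias_criterion[bias$reference == "std"])
  expect_equal(bias$pct_diff[bias$reference == "ten"], 10)
  expect_false(bias$passes_bias_criterion[bias$reference == "ten"])
  expect_true(bias$passes_bias_criterion[bias$reference == "nine"])
  expect_error(reference_bias_table(vt, "same", "missing"), "missing")
})

test_that("reference selection takes the largest passing candidate", {
  rows <- data.frame(reference = c("a", "b", "c"),
                     volume_mL = c(0.5, 10, 100),
                     n = 3, mean_VT = c(4, 4.2, 5.2),
                     pct_cov = c(12, 9, 8),
                     pct_diff = c(0.5, 5, 30),
                     passes_bias_criterion = c(TRUE, TRUE, FALSE))
  sel <- select_reference(rows,
                          data.frame(reference = c("a", "b", "c"),
                                     trv_sd = c(15, 6, 4)))
  expect_equal(sel$selected, "b")
  expect_equal(sel$report$reference, c("c", "b", "a"))  # ranked by volume
  expect_equal(sel$report$trv_sd, c(4, 6, 15))
  only_small <- rows; only_small$passes_bias_criterion <- c(TRUE, FALSE, FALSE)
  expect_equal(select_reference(only_small)$selected, "a")
  none <- rows; none$passes_bias_criterion <- FALSE
  s0 <- select_reference(none)
  expect_true(is.na(s0$selected))
  expect_match(s0$note, "no candidate")
})

test_that("sample size calculation reproduces the noncentral-t solution", {
  expect_equal(sample_size(sd = 10, delta = 10), 17)
  # independent check against the standard solver
  pt_n <- stats::power.t.test(delta = 1, sd = 1, sig.level = 0.05,
                              power = 0.80)$n
  expect_equal(sample_size(10, 10), ceiling(pt_n))
  pp <- stats::power.t.test(delta = 1, sd = 1, sig.level = 0.05,
                            power = 0.80, type = "paired")$n
  expect_equal(sample_size(10, 10, design = "paired"), ceiling(pp))
})

test_that("sample size monotonicities and limits", {
  n1 <- sample_size(10, 10)
  expect_lt(sample_size(10, 15), n1)            # larger difference: fewer
  expect_gt(sample_size(15, 10), n1)            # more variability: more
  expect_gt(sample_size(10, 10, power = 0.9), n1)
  expect_lt(sample_size(10, 10, power = 0.5), n1)
  # quadratic scaling in sd at fixed delta (large-n regime)
  nA <- sample_size(10, 3); nB <- sample_size(20, 3)
  expect_gt(nB / nA, 3.5); expect_lt(nB / nA, 4.5)
  expect_error(sample_size(0, 10), "sd must be positive")
})
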