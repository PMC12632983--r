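#' Reference-region bias table
#'
#' For each candidate reference region: mean VT and %CoV over each
#' subject's first scan, the percent difference of that mean from the
#' small-reference standard, and whether the region passes the bias
#' criterion (|percent difference| strictly below `bias_limit`).
#'
#' @param vt_table Long VT table from [compute_vt_table()] containing the
#'   reference regions.
#' @param references Character vector of reference region names.
#' @param standard_reference The comparison standard (e.g. the 2 mL
#'   deep-WM analogue); must be present in `vt_table`.
#' @param volumes_mL Optional named vector of ROI volumes for the report.
#' @param bias_limit Bias criterion threshold in percent (default 10).
#' @return data.frame: reference, volume_mL, n, mean_VT, pct_cov,
#'   pct_diff, passes_bias_criterion.
#' @export
reference_bias_table <- function(vt_table, references, standard_reference,
                                 volumes_mL = NULL, bias_limit = 10) {
  if (!standard_reference %in% vt_table$region)
    stop("standard reference '", standard_reference, "' missing from VT table")
  first <- do.call(rbind, lapply(split(vt_table, vt_table$subject),
                                 function(d) d[d$scan == min(d$scan), ]))
  refs <- unique(c(standard_reference, references))
  mean_vt <- function(r) {
    d <- first[first$region == r & first$converged & !is.na(first$VT), ]
    if (nrow(d) == 0) stop("no valid first-scan VT for reference: ", r)
    c(n = nrow(d), mean = mean(d$VT),
      cov = if (nrow(d) >= 2) percent_cov(d$VT) else NA_real_)
  }
  std <- mean_vt(standard_reference)
  rows <- lapply(refs, function(r) {
    s <- mean_vt(r)
    pd <- 100 * (s[["mean"]] - std[["mean"]]) / std[["mean"]]
    data.frame(reference = r,
               volume_mL = if (is.null(volumes_mL)) NA_real_
                           else unname(volumes_mL[r]),
               n = s[["n"]], mean_VT = s[["mean"]], pct_cov = s[["cov"]],
               pct_diff = pd,
               passes_bias_criterion = abs(pd) < bias_limit)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Select the reference region
#'
#' The selected reference is the largest-volume candidate passing the bias
#' criterion (the bias criterion is applied first; variability only breaks
#' the audit report ordering). The report lists every candidate with bias,
#' %CoV and DVR-TRV SD so the trade-off is auditable.
#'
#' @param bias_rows Output of [reference_bias_table()] (needs
#'   `volume_mL`).
#' @param trv_sds Optional data.frame with columns `reference`, `trv_sd`
#'   (SD of GM-averaged DVR TRV per reference).
#' @return List: `selected` (reference name or NA if none pass),
#'   `report` (ranked data.frame).
#' @export
select_reference <- function(bias_rows, trv_sds = NULL) {
  rep_tab <- bias_rows
  if (!is.null(trv_sds)) {
    rep_tab$trv_sd <- trv_sds$trv_sd[match(rep_tab$reference,
                                           trv_sds$reference)]
  }
  rep_tab <- rep_tab[order(-rep_tab$volume_mL), ]
  rownames(rep_tab) <- NULL
  pass <- rep_tab[rep_tab$passes_bias_criterion &
                    !is.na(rep_tab$volume_mL), ]
  selected <- if (nrow(pass)) pass$reference[which.max(pass$volume_mL)]
              else NA_character_
  note <- if (is.na(selected))
    "no candidate passes the bias criterion" else NULL
  list(selected = selected, report = rep_tab, note = note)
}

#' Regression of TRV on interscan interval
#'
#' Ordinary least squares of GM-averaged TRV on the number of days between
#' scans; tests whether variability drifts with interval.
#'
#' @param trv GM-averaged TRV per pair, percent.
#' @param interscan_days Interval per pair, days (>= 3 pairs).
#' @return List: slope (%/day), intercept (%), r_squared, p_value
#'   (two-tailed, slope = 0), rss.
#' @export
interscan_regression <- function(trv, interscan_days) {
  stopifnot(length(trv) == length(interscan_days))
  if (length(trv) < 3) stop("at least 3 pairs are required")
  fit <- stats::lm(trv ~ interscan_days)
  sm <- summary(fit)
  p <- sm$coefficients["interscan_days", "Pr(>|t|)"]
  r2 <- sm$r.squared
  if (!is.finite(r2)) r2 <- 0
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = r2,
       p_value = unname(p),
       rss = sum(stats::residuals(fit)^2))
}

#' Two-group comparison of an outcome measure
#'
#' Unpaired two-tailed t-test (pooled-variance Student test by default, to
#' match the pooled-SD effect size; Welch behind a flag), between-group
#' percent difference 100 x (mean_A - mean_B)/mean_A with A the control
#' group, Cohen's d = (mean_A - mean_B)/pooled SD with the classical
#' pooled-SD denominator (no small-sample correction), and per-group %SD.
#'
#' @param values_A Control-group values (e.g. healthy subjects).
#' @param values_B Comparison-group values (e.g. patients).
#' @param region,reference Labels carried into the output.
#' @param welch Use the Welch (unequal-variance) test instead.
#' @return Object of class `group_stats` (a one-row data.frame).
#' @export
group_compare <- function(values_A, values_B, region = NA_character_,
                          reference = NA_character_, welch = FALSE) {
  stopifnot(length(values_A) >= 2, length(values_B) >= 2)
  nA <- length(values_A); nB <- length(values_B)
  mA <- mean(values_A); mB <- mean(values_B)
  sA <- stats::sd(values_A); sB <- stats::sd(values_B)
  pooled <- sqrt(((nA - 1) * sA^2 + (nB - 1) * sB^2) / (nA + nB - 2))
  d <- if (pooled > 0) (mA - mB) / pooled else NA_real_
  if (pooled == 0 && mA == mB) {
    tt <- list(statistic = c(t = 0), p.value = 1)
    if (!welch) d <- NA_real_
  } else {
    tt <- stats::t.test(values_A, values_B, var.equal = !welch)
  }
  structure(data.frame(
    region = region, reference = reference,
    n_A = nA, n_B = nB, mean_A = mA, mean_B = mB,
    sd_A = sA, sd_B = sB,
    pct_sd_A = 100 * sA / mA, pct_sd_B = 100 * sB / mB,
    pct_diff = 100 * (mA - mB) / mA,
    t = unname(tt$statistic), p = tt$p.value, cohens_d = d,
    degenerate = pooled == 0
  ), class = c("group_stats", "data.frame"))
}

# Power of the two-tailed t-test at integer group size n, from the
# noncentral t distribution.
.t_power <- function(n, effect, alpha, design) {
  if (design == "two-sample") {
    df <- 2 * n - 2
    ncp <- effect * sqrt(n / 2)
  } else {
    df <- n - 1
    ncp <- effect * sqrt(n)
  }
  if (df < 1) return(0)
  tc <- stats::qt(1 - alpha / 2, df)
  stats::pt(tc, df, ncp, lower.tail = FALSE) + stats::pt(-tc, df, ncp)
}

#' Sample size for detecting a group difference or change
#'
#' Smallest integer group size n whose two-tailed t-test at level `alpha`
#' reaches the requested power for a true difference `delta` against
#' variability `sd` (noncentral-t power condition; `delta` and `sd` may be
#' in any common unit, e.g. percent).
#'
#' @param sd Outcome SD (> 0).
#' @param delta Difference to detect (> 0), same units as `sd`.
#' @param alpha Two-sided significance level.
#' @param power Target power.
#' @param design `"two-sample"` (difference between groups) or `"paired"`
#'   (within-subject change).
#' @param n_max Search cap.
#' @return Integer n per group (or pairs for the paired design).
#' @export
sample_size <- function(sd, delta, alpha = 0.05, power = 0.80,
                        design = c("two-sample", "paired"), n_max = 1e5) {
  design <- match.arg(design)
  if (sd <= 0) stop("sd must be positive")
  stopifnot(delta > 0, alpha > 0, alpha < 1, power > 0, power < 1)
  effect <- delta / sd
  for (n in 2:n_max) {
    if (.t_power(n, effect, alpha, design) >= power) return(n)
  }
  stop("no n <= ", n_max, " reaches the requested power")
}
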