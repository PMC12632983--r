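#' Distribution volume ratios from a VT table
#'
#' DVR = VT(target) / VT(reference) per scan. A failed or non-positive
#' reference fit invalidates every DVR of that scan (the scan is excluded
#' and the reason logged via `message`); a failed target fit drops only
#' that region. The reference never appears as its own target.
#'
#' @param vt_table Long VT table from [compute_vt_table()].
#' @param reference_region Name of the reference region in `vt_table`.
#' @param targets Optional character vector restricting target regions.
#' @return data.frame: subject, scan, group, pair_type, interscan_days,
#'   target, reference, dvr.
#' @export
compute_dvr <- function(vt_table, reference_region, targets = NULL) {
  stopifnot(reference_region %in% vt_table$region)
  ref <- vt_table[vt_table$region == reference_region, ]
  tgt <- vt_table[vt_table$region != reference_region, ]
  if (!is.null(targets)) tgt <- tgt[tgt$region %in% targets, ]
  key <- function(d) paste(d$subject, d$scan)
  bad_ref <- !ref$converged | is.na(ref$VT) | ref$VT <= 0
  if (any(bad_ref)) {
    message("excluding ", sum(bad_ref), " scan(s): reference '",
            reference_region, "' fit failed or non-positive")
    ref <- ref[!bad_ref, ]
  }
  m <- match(key(tgt), key(ref))
  keep <- !is.na(m) & tgt$converged & !is.na(tgt$VT)
  tgt <- tgt[keep, ]
  data.frame(subject = tgt$subject, scan = tgt$scan, group = tgt$group,
             pair_type = tgt$pair_type, interscan_days = tgt$interscan_days,
             target = tgt$region, reference = reference_region,
             dvr = tgt$VT / ref$VT[m[keep]],
             row.names = NULL)
}

#' Signed test-retest variability
#'
#' TRV = (retest - test) / (test + retest) x 200 percent: the signed
#' difference relative to the pair mean. Antisymmetric under swapping the
#' two values; bounded in (-200, 200) for positive inputs.
#'
#' @param test_value,retest_value Paired outcome values (vectorized).
#' @return TRV in percent.
#' @export
compute_trv <- function(test_value, retest_value) {
  s <- test_value + retest_value
  if (any(s == 0)) stop("TRV undefined: test + retest = 0")
  (retest_value - test_value) / s * 200
}

#' Pair test and retest outcomes into TRV records
#'
#' @param values Long data.frame with columns subject, scan (1 = test,
#'   2 = retest), pair_type, interscan_days, a region column `region_col`,
#'   and the outcome column `value_col`.
#' @param region_col,value_col Column names for region and outcome.
#' @param measure Label stored in the `measure` column (e.g. "VT" or
#'   "DVR_FBWM_10mL").
#' @return data.frame of TRV records: subject, region, measure, test,
#'   retest, trv_percent, pair_type, interscan_days.
#' @export
trv_records <- function(values, region_col = "region", value_col = "VT",
                        measure = value_col) {
  v1 <- values[values$scan == 1, ]
  v2 <- values[values$scan == 2, ]
  key <- function(d) paste(d$subject, d[[region_col]])
  m <- match(key(v1), key(v2))
  ok <- !is.na(m)
  v1 <- v1[ok, ]; v2 <- v2[m[ok], ]
  data.frame(subject = v1$subject, region = v1[[region_col]],
             measure = measure,
             test = v1[[value_col]], retest = v2[[value_col]],
             trv_percent = compute_trv(v1[[value_col]], v2[[value_col]]),
             pair_type = v1$pair_type,
             interscan_days = v2$interscan_days,
             row.names = NULL)
}

#' Summarize TRV records
#'
#' Mean and sample SD (n - 1 denominator) of TRV over subjects per
#' (region, pair_type, measure) cell; cells with fewer than 2 records are
#' omitted with a warning.
#'
#' @param records TRV records from [trv_records()].
#' @param by Grouping columns.
#' @return data.frame with n, mean_trv, sd_trv per group.
#' @export
summarize_trv <- function(records, by = c("region", "pair_type", "measure")) {
  f <- interaction(records[by], drop = TRUE, lex.order = TRUE)
  out <- do.call(rbind, lapply(split(records, f), function(d) {
    cbind(d[1, by, drop = FALSE],
          data.frame(n = nrow(d),
                     mean_trv = mean(d$trv_percent),
                     sd_trv = if (nrow(d) >= 2) stats::sd(d$trv_percent)
                              else NA_real_))
  }))
  drop <- out$n < 2
  if (any(drop)) {
    warning(sum(drop), " cell(s) with fewer than 2 records omitted")
    out <- out[!drop, ]
  }
  rownames(out) <- NULL
  out
}

#' Gray-matter-averaged TRV per subject
#'
#' First averages TRV within subject across the 12 evaluated gray-matter
#' regions (one value per scan pair - the quantity plotted against
#' interscan interval), then summarizes across subjects. Averaging within
#' subject first differs from pooling all region-level records; the
#' within-subject-first order is the one used throughout.
#'
#' @param records TRV records from [trv_records()].
#' @param gm_regions Regions to average over (default the 12 GM regions).
#' @return List: `per_subject` data.frame (subject, pair_type,
#'   interscan_days, measure, gm_trv) and `summary` (n, mean, sd per
#'   pair_type x measure).
#' @export
gm_average_trv <- function(records, gm_regions = GM_REGIONS) {
  d <- records[records$region %in% gm_regions, ]
  f <- interaction(d$subject, d$measure, drop = TRUE)
  per <- do.call(rbind, lapply(split(d, f), function(x) {
    data.frame(subject = x$subject[1], pair_type = x$pair_type[1],
               interscan_days = x$interscan_days[1],
               measure = x$measure[1], gm_trv = mean(x$trv_percent))
  }))
  rownames(per) <- NULL
  g <- interaction(per$pair_type, per$measure, drop = TRUE)
  smry <- do.call(rbind, lapply(split(per, g), function(x) {
    data.frame(pair_type = x$pair_type[1], measure = x$measure[1],
               n = nrow(x), mean_trv = mean(x$gm_trv),
               sd_trv = if (nrow(x) >= 2) stats::sd(x$gm_trv) else NA_real_)
  }))
  rownames(smry) <- NULL
  list(per_subject = per, summary = smry)
}

#' Percent coefficient of variation
#'
#' 100 x sample SD (n - 1 denominator) / mean.
#'
#' @param values Numeric vector, n >= 2, mean != 0.
#' @export
percent_cov <- function(values) {
  stopifnot(length(values) >= 2)
  m <- mean(values)
  if (m == 0) stop("%CoV undefined for zero mean")
  100 * stats::sd(values) / m
}
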