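#' Time-activity curve
#'
#' Frame-wise mean tissue activity concentration (kBq/cm^3) on a frame
#' schedule.
#'
#' @param schedule A [frame_schedule()].
#' @param values Numeric vector, one activity value per frame.
#' @export
tac <- function(schedule, values) {
  stopifnot(inherits(schedule, "frame_schedule"),
            length(values) == nrow(schedule), all(is.finite(values)))
  structure(list(schedule = schedule, values = values), class = "tac")
}

# Precomputed quantities shared by every model evaluation for one
# (input function, schedule) pair: integration nodes, node plasma values,
# running plasma integral, and frame-boundary node indices.
.onetcm_context <- function(cp, schedule) {
  stopifnot(inherits(cp, "input_function"), inherits(schedule, "frame_schedule"))
  t_max <- max(schedule$frame_end_min)
  nodes <- c(0, cp$time_min[cp$time_min <= t_max],
             schedule$frame_start_min, schedule$frame_end_min)
  if (max(cp$time_min) < t_max) {
    nodes <- c(nodes, seq(max(cp$time_min), t_max, by = 0.25))
  }
  nodes <- sort(unique(nodes))
  cv <- eval_input(cp, nodes)
  h <- diff(nodes)
  # running integral of the piecewise-linear plasma curve
  Q <- c(0, cumsum((cv[-1] + cv[-length(cv)]) / 2 * h))
  ia <- vapply(schedule$frame_start_min,
               function(t) which.min(abs(nodes - t)), integer(1))
  ib <- vapply(schedule$frame_end_min,
               function(t) which.min(abs(nodes - t)), integer(1))
  list(nodes = nodes, h = h, cv = cv, Q = Q, ia = ia, ib = ib,
       dur = frame_durations(schedule), schedule = schedule)
}

# Frame-averaged one-tissue model with K1 = 1 (model is linear in K1).
# Exact closed form: C(t) = int_0^t exp(-k2 (t-s)) cp(s) ds with cp
# piecewise linear between nodes; the frame average follows from the
# compartment ODE, int_a^b C dt = (Q(b) - Q(a) - (C(b) - C(a))) / k2.
.onetcm_basis <- function(k2, ctx) {
  h <- ctx$h
  n <- length(h)
  c0 <- ctx$cv[-(n + 1)]
  c1 <- ctx$cv[-1]
  E1 <- -expm1(-k2 * h) / k2
  E2 <- (h - E1) / k2
  s <- (c1 - c0) / h
  b <- c0 * E1 + s * E2
  a <- exp(-k2 * h)
  P <- cumprod(a)
  if (min(P) > 1e-280) {
    C <- c(0, P * cumsum(b / P))
  } else {
    C <- numeric(n + 1)
    for (j in seq_len(n)) C[j + 1] <- a[j] * C[j] + b[j]
  }
  (ctx$Q[ctx$ib] - ctx$Q[ctx$ia] - (C[ctx$ib] - C[ctx$ia])) /
    (k2 * ctx$dur)
}

#' One-tissue-compartment model prediction
#'
#' Tissue concentration C(t) = K1 * int_0^t exp(-k2 (t - s)) cp(s) ds,
#' evaluated by the exact closed-form convolution of an exponential with
#' the piecewise-linear input curve; each frame value is the time average
#' of C(t) over the frame (not a midpoint sample; frames up to 5 min make
#' midpoint bias non-negligible).
#'
#' @param K1 Influx rate, mL/cm^3/min (>= 0).
#' @param k2 Efflux rate, 1/min (> 0).
#' @param cp An [input_function()].
#' @param schedule A [frame_schedule()].
#' @return A [tac()].
#' @export
onetcm_predict <- function(K1, k2, cp, schedule) {
  if (k2 <= 0) stop("k2 must be positive")
  stopifnot(K1 >= 0)
  ctx <- .onetcm_context(cp, schedule)
  tac(schedule, K1 * .onetcm_basis(k2, ctx))
}

#' Fit the one-tissue-compartment model to a TAC
#'
#' Weighted least squares on the frame-averaged model. K1 enters linearly
#' and is profiled out in closed form; the weighted residual sum of squares
#' is then minimized over k2 alone by a deterministic log-spaced coarse
#' grid followed by golden-section refinement within the parameter bounds
#' (K1 in [1e-4, 5] mL/cm^3/min, k2 in [1e-4, 2] /min). The fit is fully
#' deterministic. VT = K1/k2. A fit whose optimum pins either parameter to
#' a bound is flagged as not converged and its VT marked invalid (NA).
#'
#' @param tac_obj A [tac()].
#' @param cp An [input_function()].
#' @param weights Frame weights; default frame durations
#'   (uniform-variance-per-unit-time proxy). `"uniform"` for equal weights.
#' @return Object of class `kinetic_fit` with fields `K1`, `k2`, `VT`,
#'   `wrss`, `converged`, `se` (standard errors from the fit curvature).
#' @export
fit_onetcm <- function(tac_obj, cp, weights = NULL) {
  stopifnot(inherits(tac_obj, "tac"))
  y <- tac_obj$values
  if (length(y) < 4) stop("at least 4 frames are required")
  ctx <- .onetcm_context(cp, tac_obj$schedule)
  w <- weights
  if (is.null(w)) w <- ctx$dur
  if (identical(w, "uniform")) w <- rep(1, length(y))
  stopifnot(length(w) == length(y), all(w > 0))

  k2_lo <- 1e-4; k2_hi <- 2; K1_lo <- 1e-4; K1_hi <- 5

  prof <- function(k2) {
    M <- .onetcm_basis(k2, ctx)
    den <- sum(w * M^2)
    K1 <- if (den > 0) sum(w * y * M) / den else 0
    K1 <- min(max(K1, K1_lo), K1_hi)
    r <- y - K1 * M
    list(K1 = K1, wrss = sum(w * r^2), M = M)
  }
  grid <- exp(seq(log(k2_lo), log(k2_hi), length.out = 30))
  wg <- vapply(grid, function(k) prof(k)$wrss, numeric(1))
  i0 <- which.min(wg)
  lo <- grid[max(1L, i0 - 1L)]
  hi <- grid[min(length(grid), i0 + 1L)]
  opt <- stats::optimize(function(k) prof(k)$wrss, c(lo, hi), tol = 1e-9)
  k2 <- if (opt$objective <= wg[i0]) opt$minimum else grid[i0]
  pf <- prof(k2)
  K1 <- pf$K1

  at_bound <- (k2 - k2_lo) < 1e-6 || (k2_hi - k2) < 1e-6 ||
    K1 <= K1_lo || K1 >= K1_hi
  converged <- is.finite(pf$wrss) && !at_bound

  # curvature-based standard errors: J columns d/dK1, d/dk2
  se <- c(K1 = NA_real_, k2 = NA_real_)
  if (converged && length(y) > 2) {
    dk <- max(1e-6, 1e-4 * k2)
    dM <- (.onetcm_basis(k2 + dk, ctx) - .onetcm_basis(k2 - dk, ctx)) / (2 * dk)
    J <- cbind(pf$M, K1 * dM)
    sigma2 <- pf$wrss / (length(y) - 2)
    H <- crossprod(J, w * J)
    cv <- tryCatch(solve(H) * sigma2, error = function(e) NULL)
    if (!is.null(cv) && all(diag(cv) >= 0)) {
      se <- c(K1 = sqrt(cv[1, 1]), k2 = sqrt(cv[2, 2]))
    }
  }
  structure(list(K1 = K1, k2 = k2,
                 VT = if (converged) K1 / k2 else NA_real_,
                 wrss = pf$wrss, converged = converged, se = se),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("1TCM fit: K1 = %.4f, k2 = %.5f, VT = %.3f (%s)\n",
              x$K1, x$k2, x$K1 / x$k2,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Batch VT estimation over scans and regions
#'
#' Applies [fit_onetcm()] to every (scan, region) pair and collects a long
#' table. Failed fits are recorded with `converged = FALSE` and `VT = NA`,
#' never silently dropped.
#'
#' @param scans List of scan entries. Each entry is a list with fields
#'   `subject`, `scan`, `input` (an [input_function()]), `tacs` (named list
#'   of [tac()] objects, one per region), and optionally `group`,
#'   `pair_type`, `interscan_days`.
#' @param weights Passed to [fit_onetcm()].
#' @return data.frame with one row per (scan, region): subject, scan,
#'   group, pair_type, interscan_days, region, K1, k2, VT, wrss, converged.
#' @export
compute_vt_table <- function(scans, weights = NULL) {
  rows <- lapply(scans, function(sc) {
    stopifnot(!is.null(sc$tacs), !is.null(sc$input))
    regions <- names(sc$tacs)
    if (anyDuplicated(regions)) stop("duplicate region names in scan ",
                                     sc$subject, "/", sc$scan)
    fits <- lapply(sc$tacs, fit_onetcm, cp = sc$input, weights = weights)
    data.frame(
      subject = sc$subject,
      scan = sc$scan,
      group = if (is.null(sc$group)) NA_character_ else sc$group,
      pair_type = if (is.null(sc$pair_type)) NA_character_ else sc$pair_type,
      interscan_days = if (is.null(sc$interscan_days)) NA_real_ else sc$interscan_days,
      region = regions,
      K1 = vapply(fits, `[[`, numeric(1), "K1"),
      k2 = vapply(fits, `[[`, numeric(1), "k2"),
      VT = vapply(fits, `[[`, numeric(1), "VT"),
      wrss = vapply(fits, `[[`, numeric(1), "wrss"),
      converged = vapply(fits, `[[`, logical(1), "converged"),
      row.names = NULL
    )
  })
  do.call(rbind, rows)
}
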