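#' Frame schedule
#'
#' @param frame_start_min,frame_end_min Frame boundaries in minutes; starts
#'   strictly increasing, end > start, frames non-overlapping.
#' @return Object of class `frame_schedule` (data.frame with the two
#'   columns plus a `mid_min` convenience column).
#' @export
frame_schedule <- function(frame_start_min, frame_end_min) {
  stopifnot(length(frame_start_min) == length(frame_end_min),
            all(is.finite(frame_start_min)), all(is.finite(frame_end_min)))
  if (any(diff(frame_start_min) <= 0))
    stop("frame starts must be strictly increasing")
  if (any(frame_end_min <= frame_start_min))
    stop("frame end must exceed frame start")
  if (any(frame_start_min[-1] < frame_end_min[-length(frame_end_min)]))
    stop("frames must not overlap")
  structure(data.frame(frame_start_min = frame_start_min,
                       frame_end_min = frame_end_min,
                       mid_min = (frame_start_min + frame_end_min) / 2),
            class = c("frame_schedule", "data.frame"))
}

#' Default 60-min frame schedule
#'
#' 6 x 0.5, 3 x 1, 2 x 2, 10 x 5 min (21 frames, 60 min total); shorter
#' early frames capture the input-function peak.
#' @export
default_frame_schedule <- function() {
  dur <- c(rep(0.5, 6), rep(1, 3), rep(2, 2), rep(5, 10))
  ends <- cumsum(dur)
  frame_schedule(ends - dur, ends)
}

#' Frame durations in minutes
#' @param schedule A `frame_schedule`.
#' @export
frame_durations <- function(schedule) {
  schedule$frame_end_min - schedule$frame_start_min
}

#' Arterial input function
#'
#' A sampled metabolite-corrected plasma concentration curve. Between
#' samples the curve is piecewise linear; before the first sample it is 0;
#' after the last sample it decays single-exponentially at the rate fitted
#' from the last two samples (flat if that rate is not positive).
#'
#' @param time_min Strictly increasing sample times (min), first >= 0.
#' @param cp Plasma concentration (kBq/mL), non-negative.
#' @return Object of class `input_function`.
#' @export
input_function <- function(time_min, cp) {
  stopifnot(length(time_min) == length(cp), length(cp) >= 2)
  if (any(diff(time_min) <= 0)) stop("time grid must be strictly increasing")
  if (time_min[1] < 0) stop("time grid must start at or after 0")
  if (any(cp < 0)) stop("plasma concentrations must be non-negative")
  n <- length(cp)
  tail_rate <- 0
  if (cp[n] > 0 && cp[n - 1] > cp[n]) {
    tail_rate <- log(cp[n - 1] / cp[n]) / (time_min[n] - time_min[n - 1])
  }
  structure(list(time_min = time_min, cp = cp, tail_rate = tail_rate),
            class = "input_function")
}

#' Evaluate an input function
#' @param cp An `input_function`.
#' @param t Times (min) at which to evaluate.
#' @export
eval_input <- function(cp, t) {
  stopifnot(inherits(cp, "input_function"))
  n <- length(cp$time_min)
  out <- stats::approx(cp$time_min, cp$cp, xout = t, rule = 1)$y
  out[t < cp$time_min[1]] <- 0
  late <- t > cp$time_min[n]
  if (any(late)) {
    out[late] <- cp$cp[n] * exp(-cp$tail_rate * (t[late] - cp$time_min[n]))
  }
  out
}

#' Simulate an arterial input function
#'
#' Linear rise from 0 at t = 0 to `peak_value` at `peak_time_min`, followed
#' by a weighted sum of decaying exponentials, continuous at the peak
#' (weights are normalized so the curve equals `peak_value` at the peak).
#' The curve is returned sampled on a fine grid: `rise_dt_min` spacing up to
#' 5 min, then `tail_dt_min` spacing to `t_max_min`.
#'
#' @param peak_time_min Time of the plasma peak (> 0), min.
#' @param peak_value Peak plasma concentration, kBq/mL.
#' @param decay_rates Distinct positive decay rates, 1/min.
#' @param decay_weights Positive weights, same length as `decay_rates`.
#' @param t_max_min Last sample time, min.
#' @param rise_dt_min,tail_dt_min Sampling steps, min.
#' @return An [input_function()].
#' @export
simulate_input_function <- function(peak_time_min = 1.5, peak_value = 100,
                                    decay_rates = c(3, 0.25, 0.015),
                                    decay_weights = c(0.7, 0.25, 0.05),
                                    t_max_min = 60,
                                    rise_dt_min = 0.05, tail_dt_min = 0.25) {
  stopifnot(peak_time_min > 0, peak_value > 0,
            all(decay_rates > 0), all(decay_weights > 0),
            length(decay_rates) == length(decay_weights),
            !anyDuplicated(decay_rates))
  w <- decay_weights / sum(decay_weights)
  tt <- sort(unique(c(seq(0, min(5, t_max_min), by = rise_dt_min),
                      seq(min(5, t_max_min), t_max_min, by = tail_dt_min),
                      peak_time_min, t_max_min)))
  vals <- numeric(length(tt))
  rise <- tt <= peak_time_min
  vals[rise] <- peak_value * tt[rise] / peak_time_min
  td <- tt[!rise] - peak_time_min
  vals[!rise] <- peak_value *
    colSums(w * exp(-outer(decay_rates, td)))
  input_function(tt, vals)
}

#' Read/write a frame schedule as TSV
#' @param path File path.
#' @param schedule A `frame_schedule`.
#' @export
write_schedule_tsv <- function(schedule, path) {
  utils::write.table(schedule[c("frame_start_min", "frame_end_min")], path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_schedule_tsv
#' @export
read_schedule_tsv <- function(path) {
  d <- utils::read.delim(path)
  frame_schedule(d$frame_start_min, d$frame_end_min)
}

#' Read/write an input function as TSV
#' @param path File path.
#' @param cp An `input_function`.
#' @export
write_input_tsv <- function(cp, path) {
  utils::write.table(
    data.frame(time_min = cp$time_min, plasma_kBq_per_mL = cp$cp), path,
    sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_input_tsv
#' @export
read_input_tsv <- function(path) {
  d <- utils::read.delim(path)
  input_function(d$time_min, d$plasma_kBq_per_mL)
}
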