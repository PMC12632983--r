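#' Dynamic PET image
#'
#' @param data 4-D array, voxel x frame activity concentration (kBq/cm^3).
#' @param schedule A [frame_schedule()] with one row per frame.
#' @param voxel_size_mm Voxel edge lengths, mm.
#' @param provenance List recording seed and generation parameters.
#' @export
dynamic_image <- function(data, schedule, voxel_size_mm, provenance = list()) {
  stopifnot(length(dim(data)) == 4L, inherits(schedule, "frame_schedule"))
  if (dim(data)[4] != nrow(schedule))
    stop("frame axis length (", dim(data)[4], ") does not match schedule (",
         nrow(schedule), " frames)")
  if (!all(is.finite(data))) stop("non-finite voxel values")
  structure(list(data = data, schedule = schedule,
                 voxel_size_mm = rep_len(voxel_size_mm, 3L),
                 provenance = provenance),
            class = "dynamic_image")
}

#' @export
print.dynamic_image <- function(x, ...) {
  cat("dynamic_image:", paste(dim(x$data), collapse = " x "),
      "(voxels x frames)\n")
  invisible(x)
}

# Noise-free frame-averaged region TACs as a regions x frames matrix.
.region_tac_matrix <- function(truth, cp, schedule) {
  ctx <- .onetcm_context(cp, schedule)
  rows <- lapply(names(truth$K1),
                 function(r) truth$K1[[r]] * .onetcm_basis(truth$k2[[r]], ctx))
  out <- do.call(rbind, rows)
  rownames(out) <- names(truth$K1)
  out
}

#' Simulate a dynamic PET scan of the phantom
#'
#' Forward model: each region follows noise-free one-tissue-compartment
#' kinetics (frame-averaged); per frame, the voxel image is the piecewise
#' constant region image convolved with a 3-D Gaussian point-spread
#' function of the given FWHM (spill-in), plus independent zero-mean
#' Gaussian noise with SD = noise_scale * sqrt(C(t)/dt) per voxel-frame
#' (count-statistics proxy: shorter frames and hotter voxels are noisier;
#' decay correction is assumed already applied).
#'
#' @param labels A `label_volume`.
#' @param truth A [kinetic_truth()] covering every labelled region.
#' @param cp An [input_function()].
#' @param schedule A [frame_schedule()].
#' @param psf_fwhm_mm Point-spread FWHM, mm (0 disables blurring).
#' @param noise_scale Noise magnitude (0 disables noise); units make
#'   noise_scale^2 * C/dt a variance in (kBq/cm^3)^2.
#' @param seed Integer seed; the image is bit-reproducible given the seed.
#' @return A [dynamic_image()].
#' @export
simulate_dynamic_pet <- function(labels, truth, cp, schedule,
                                 psf_fwhm_mm = 9, noise_scale = 0,
                                 seed = 1L) {
  force(seed)  # evaluate before any RNG state is saved
  stopifnot(inherits(labels, "label_volume"), inherits(truth, "kinetic_truth"))
  lab_regions <- names(labels$code_map)
  missing <- setdiff(lab_regions, names(truth$K1))
  if (length(missing))
    stop("regions missing from kinetic truth: ", paste(missing, collapse = ", "))

  tacs <- .region_tac_matrix(truth, cp, schedule)
  nf <- nrow(schedule)
  d3 <- dim(labels$labels)

  # lookup region TAC by label code (code 0 = background = 0 activity)
  lut <- matrix(0, max(labels$code_map) + 1L, nf)
  for (r in lab_regions) lut[labels$code_map[[r]] + 1L, ] <- tacs[r, ]
  idx <- as.vector(labels$labels) + 1L

  dat <- array(0, c(d3, nf))
  dur <- frame_durations(schedule)
  if (noise_scale > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
  }
  for (f in seq_len(nf)) {
    fr <- array(lut[idx, f], d3)
    if (psf_fwhm_mm > 0)
      fr <- smooth_gaussian_3d(fr, psf_fwhm_mm, labels$voxel_size_mm)
    if (noise_scale > 0) {
      sd_vox <- noise_scale * sqrt(pmax(fr, 0) / dur[f])
      fr <- fr + stats::rnorm(length(fr), 0, as.vector(sd_vox))
    }
    dat[, , , f] <- fr
  }
  dynamic_image(dat, schedule, labels$voxel_size_mm,
                provenance = list(seed = seed, psf_fwhm_mm = psf_fwhm_mm,
                                  noise_scale = noise_scale))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Cohort specification
#'
#' Study-design parameters for synthetic test-retest and case-control
#' cohorts. Defaults mirror the emulated study: 30 healthy-subject (HS)
#' test-retest scan pairs (10 same-day, 20 longitudinal allocated 4/5/11
#' to the 7-30, 30-365 and 365-1028 day interval strata) and 20
#' single-scan Parkinson's disease (PD) subjects with binding reduced in
#' substantia nigra, caudate and brainstem.
#'
#' Variance components (all multiplicative lognormal on VT via K1, k2
#' fixed): `between_subject_cv` and `within_subject_cv` act independently
#' per region (regional biology); `subject_scale_cv` and `scan_scale_cv`
#' are global factors per subject and per scan (body-wide differences and
#' instrumental calibration) that cancel exactly in DVR - the reason DVR
#' is the preferred outcome measure.
#'
#' @param n_HS Number of HS test-retest scan pairs (>= 2).
#' @param n_PD Number of PD subjects (>= 2).
#' @param n_same_day How many HS pairs are same-day (interval 0 days).
#' @param pd_effect Fractional VT reduction in PD regions (0 <= x < 1).
#' @param between_subject_cv Per-region between-subject CV.
#' @param within_subject_cv Per-region test-vs-retest CV.
#' @param subject_scale_cv Global per-subject CV (cancels in DVR).
#' @param scan_scale_cv Global per-scan CV (cancels in DVR).
#' @param interscan_days_range Bounds (days) for longitudinal intervals.
#' @param longitudinal_strata Proportions over interval strata
#'   7-30 / 30-365 / 365-max days.
#' @param psf_fwhm_mm Scanner point-spread FWHM, mm.
#' @param noise_scale Voxel noise magnitude, see [simulate_dynamic_pet()].
#' @param seed Master seed; all cohort randomness derives from it.
#' @export
cohort_spec <- function(n_HS = 30L, n_PD = 20L,
                        n_same_day = max(0L, round(n_HS / 3)),
                        pd_effect = 0.10,
                        between_subject_cv = 0.08,
                        within_subject_cv = 0.025,
                        subject_scale_cv = 0.05,
                        scan_scale_cv = 0.06,
                        interscan_days_range = c(7, 1028),
                        longitudinal_strata = c(4, 5, 11) / 20,
                        psf_fwhm_mm = 9,
                        noise_scale = 18,
                        seed = 1L) {
  spec <- structure(as.list(environment()), class = "cohort_spec")
  errs <- validate_cohort_spec(spec)
  if (length(errs)) stop(paste(errs, collapse = "; "))
  spec
}

#' Validate a cohort specification
#' @param spec A [cohort_spec()] (or plain list with the same fields).
#' @return Character vector of violations (length 0 when valid).
#' @export
validate_cohort_spec <- function(spec) {
  errs <- character()
  chk <- function(cond, msg) if (!isTRUE(cond)) errs <<- c(errs, msg)
  chk(spec$n_HS >= 2, "n_HS must be >= 2")
  chk(spec$n_PD >= 2, "n_PD must be >= 2")
  chk(spec$n_same_day >= 0 && spec$n_same_day <= spec$n_HS,
      "n_same_day must be in [0, n_HS]")
  chk(spec$pd_effect >= 0 && spec$pd_effect < 1,
      "pd_effect must be in [0, 1)")
  for (f in c("between_subject_cv", "within_subject_cv",
              "subject_scale_cv", "scan_scale_cv"))
    chk(spec[[f]] >= 0, paste(f, "must be >= 0"))
  chk(spec$psf_fwhm_mm >= 0, "psf_fwhm_mm must be >= 0")
  chk(spec$noise_scale >= 0, "noise_scale must be >= 0")
  chk(length(spec$interscan_days_range) == 2 &&
        diff(spec$interscan_days_range) > 0,
      "interscan_days_range must be increasing bounds")
  errs
}

# Deterministic substream seeds: adding subjects or scans never perturbs
# existing ones. purpose 0 = design draws, 1 = kinetic multipliers,
# 2 = voxel noise.
.substream_seed <- function(master, subject, scan = 0L, purpose = 0L) {
  as.integer((as.double(master) * 2654435761 +
                subject * 1000003 + scan * 10007 + purpose * 97) %%
               2147483647)
}

.lognormal_mult <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdl <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, -sdl^2 / 2, sdl))
}

#' Simulate a test-retest + case-control cohort
#'
#' Draws per-subject and per-scan kinetic ground truths from the master
#' seed via a documented substream scheme and returns a cohort object of
#' scan descriptors; 4-D images are realized lazily with
#' [realize_scan_image()] (a 30-pair cohort would not fit in memory all at
#' once) and ROI TACs can be produced exactly without images via
#' [cohort_roi_tacs()].
#'
#' HS subjects get two scans whose per-region VT multipliers are the
#' subject-level values times independent lognormal within-subject
#' factors; PD subjects get one scan with VT scaled by (1 - pd_effect) in
#' substantia nigra, caudate and brainstem only.
#'
#' @param phantom A [phantom_spec()].
#' @param truth A [kinetic_truth()].
#' @param cohort A [cohort_spec()].
#' @param cp Optional [input_function()]; default the standard synthetic
#'   input curve.
#' @param schedule Optional [frame_schedule()]; default
#'   [default_frame_schedule()].
#' @return Object of class `pet_cohort`: `scans` data.frame (subject,
#'   group, scan, pair_type, interscan_days, noise seed) and per-scan
#'   kinetic truths in `scan_truths`.
#' @export
simulate_cohort <- function(phantom, truth, cohort,
                            cp = simulate_input_function(),
                            schedule = default_frame_schedule()) {
  stopifnot(inherits(phantom, "phantom_spec"), inherits(truth, "kinetic_truth"),
            inherits(cohort, "cohort_spec"))
  regions <- names(truth$K1)
  nr <- length(regions)
  scans <- list()
  scan_truths <- list()
  master <- cohort$seed

  add_scan <- function(subject, group, scan, pair_type, days, K1mult) {
    i <- length(scans) + 1L
    scans[[i]] <<- data.frame(
      subject = subject, group = group, scan = scan,
      pair_type = pair_type, interscan_days = days,
      noise_seed = .substream_seed(master, match(subject, subj_ids), scan, 2L))
    st <- truth
    st$K1 <- truth$K1 * K1mult
    st$VT <- st$K1 / st$k2
    scan_truths[[i]] <<- st
  }

  n_hs <- cohort$n_HS
  n_pd <- cohort$n_PD
  subj_ids <- c(sprintf("HS%02d", seq_len(n_hs)), sprintf("PD%02d", seq_len(n_pd)))

  # interval design: same-day pairs first, then stratified longitudinal
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  for (i in seq_len(n_hs)) {
    sid <- subj_ids[i]
    set.seed(.substream_seed(master, i, 0L, 0L))
    if (i <= cohort$n_same_day) {
      pair_type <- "same_day"; days <- 0
    } else {
      pair_type <- "longitudinal"
      lo <- cohort$interscan_days_range[1]
      hi <- cohort$interscan_days_range[2]
      edges <- c(lo, min(30, hi), min(365, hi), hi)
      stratum <- sample.int(3L, 1L, prob = cohort$longitudinal_strata)
      days <- stats::runif(1, edges[stratum], edges[stratum + 1])
    }
    set.seed(.substream_seed(master, i, 0L, 1L))
    subj_mult <- .lognormal_mult(nr, cohort$between_subject_cv) *
      .lognormal_mult(1, cohort$subject_scale_cv)
    for (s in 1:2) {
      set.seed(.substream_seed(master, i, s, 1L))
      scan_mult <- .lognormal_mult(nr, cohort$within_subject_cv) *
        .lognormal_mult(1, cohort$scan_scale_cv)
      add_scan(sid, "HS", s, pair_type, days,
               stats::setNames(subj_mult * scan_mult, regions))
    }
  }
  pd_factor <- stats::setNames(rep(1, nr), regions)
  pd_factor[intersect(PD_REGIONS, regions)] <- 1 - cohort$pd_effect
  for (j in seq_len(n_pd)) {
    i <- n_hs + j
    sid <- subj_ids[i]
    set.seed(.substream_seed(master, i, 0L, 1L))
    subj_mult <- .lognormal_mult(nr, cohort$between_subject_cv) *
      .lognormal_mult(1, cohort$subject_scale_cv)
    set.seed(.substream_seed(master, i, 1L, 1L))
    scan_mult <- .lognormal_mult(nr, cohort$within_subject_cv) *
      .lognormal_mult(1, cohort$scan_scale_cv)
    add_scan(sid, "PD", 1L, "single", NA_real_,
             stats::setNames(subj_mult * scan_mult * pd_factor, regions))
  }

  structure(list(
    phantom = phantom, truth = truth, cohort = cohort,
    cp = cp, schedule = schedule,
    scans = do.call(rbind, scans),
    scan_truths = scan_truths
  ), class = "pet_cohort")
}

#' @export
print.pet_cohort <- function(x, ...) {
  cat("pet_cohort:", nrow(x$scans), "scans (",
      sum(x$scans$group == "HS"), "HS,", sum(x$scans$group == "PD"), "PD )\n")
  invisible(x)
}

#' Realize the 4-D image for one cohort scan
#'
#' @param cohort A `pet_cohort`.
#' @param i Scan row index into `cohort$scans`.
#' @param labels Prebuilt label volume for `cohort$phantom` (built on the
#'   fly if omitted).
#' @return A [dynamic_image()].
#' @export
realize_scan_image <- function(cohort, i, labels = NULL) {
  stopifnot(inherits(cohort, "pet_cohort"))
  if (is.null(labels)) labels <- build_phantom(cohort$phantom)
  simulate_dynamic_pet(labels, cohort$scan_truths[[i]], cohort$cp,
                       cohort$schedule,
                       psf_fwhm_mm = cohort$cohort$psf_fwhm_mm,
                       noise_scale = cohort$cohort$noise_scale,
                       seed = cohort$scans$noise_seed[i])
}
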