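#' PSF cross-talk matrix between regions and ROIs
#'
#' For each source region r, smooth its binary indicator with the scanner
#' point-spread function and average the result over each ROI:
#' A[roi, r] = mean over roi voxels of PSF(indicator_r). Because the image
#' forward model is linear, the ROI-mean of any noise-free dynamic image is
#' exactly A %*% (region TAC matrix). Together with the per-ROI voxel
#' counts this makes ROI-level simulation distributionally identical to
#' voxel-level simulation (voxel noise is added after the PSF,
#' independently per voxel, so the ROI-mean noise SD is
#' noise_scale * sqrt(mean C/dt) / sqrt(n_vox)).
#'
#' @param labels A `label_volume`.
#' @param rois Named list of [roi_mask()].
#' @param psf_fwhm_mm Point-spread FWHM, mm (0 = no blurring).
#' @return Object of class `roi_crosstalk`: matrix `A` (roi x region),
#'   integer vector `n_vox`, and the region names.
#' @export
roi_crosstalk <- function(labels, rois, psf_fwhm_mm = 9) {
  stopifnot(inherits(labels, "label_volume"), length(rois) > 0)
  regions <- names(labels$code_map)
  roi_idx <- lapply(rois, function(r) {
    stopifnot(inherits(r, "roi_mask"))
    which(as.vector(r$mask))
  })
  A <- matrix(0, length(rois), length(regions),
              dimnames = list(names(rois), regions))
  for (r in regions) {
    ind <- (labels$labels == labels$code_map[[r]]) * 1
    if (psf_fwhm_mm > 0)
      ind <- smooth_gaussian_3d(ind, psf_fwhm_mm, labels$voxel_size_mm)
    v <- as.vector(ind)
    A[, r] <- vapply(roi_idx, function(ix) mean(v[ix]), numeric(1))
  }
  structure(list(A = A,
                 n_vox = vapply(roi_idx, length, integer(1)),
                 regions = regions),
            class = "roi_crosstalk")
}

#' ROI-level TACs for one scan (image-free shortcut)
#'
#' Computes the exact noise-free ROI-mean TACs via the cross-talk matrix
#' and adds ROI-level Gaussian noise with the variance the voxel-level
#' model would induce on the ROI mean. Used for replicate loops where
#' realizing full 4-D images would be wasteful.
#'
#' @param ct A [roi_crosstalk()].
#' @param truth A [kinetic_truth()] (per-scan, multipliers applied).
#' @param cp An [input_function()].
#' @param schedule A [frame_schedule()].
#' @param noise_scale,seed As in [simulate_dynamic_pet()].
#' @return Named list of [tac()] objects, one per ROI.
#' @export
simulate_roi_tacs <- function(ct, truth, cp, schedule,
                              noise_scale = 0, seed = 1L) {
  force(seed)  # evaluate before any RNG state is saved
  stopifnot(inherits(ct, "roi_crosstalk"))
  missing <- setdiff(ct$regions, names(truth$K1))
  if (length(missing))
    stop("regions missing from kinetic truth: ", paste(missing, collapse = ", "))
  tacs <- .region_tac_matrix(truth, cp, schedule)[ct$regions, , drop = FALSE]
  roi_vals <- ct$A %*% tacs
  if (noise_scale > 0) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    dur <- frame_durations(schedule)
    sd <- noise_scale * sqrt(pmax(roi_vals, 0) %*% diag(1 / dur)) /
      sqrt(ct$n_vox)
    roi_vals <- roi_vals + stats::rnorm(length(roi_vals), 0, as.vector(sd))
  }
  stats::setNames(
    lapply(seq_len(nrow(roi_vals)), function(i) tac(schedule, roi_vals[i, ])),
    rownames(roi_vals))
}

#' ROI TACs for every scan of a cohort
#'
#' Produces the scan-entry list consumed by [compute_vt_table()], either by
#' realizing each 4-D image and extracting ROI means (`method = "image"`)
#' or via the exact ROI-level shortcut (`method = "roi"`). Images are
#' processed one at a time and discarded.
#'
#' @param cohort A `pet_cohort` from [simulate_cohort()].
#' @param rois Named list of [roi_mask()].
#' @param method `"image"` or `"roi"`.
#' @param labels Prebuilt label volume (built if omitted).
#' @param ct Prebuilt [roi_crosstalk()] (built if omitted; only for
#'   `method = "roi"`).
#' @return List of scan entries (subject, scan, group, pair_type,
#'   interscan_days, input, tacs).
#' @export
cohort_roi_tacs <- function(cohort, rois, method = c("roi", "image"),
                            labels = NULL, ct = NULL) {
  method <- match.arg(method)
  if (is.null(labels)) labels <- build_phantom(cohort$phantom)
  if (method == "roi" && is.null(ct))
    ct <- roi_crosstalk(labels, rois, cohort$cohort$psf_fwhm_mm)
  lapply(seq_len(nrow(cohort$scans)), function(i) {
    row <- cohort$scans[i, ]
    tacs <- if (method == "roi") {
      simulate_roi_tacs(ct, cohort$scan_truths[[i]], cohort$cp,
                        cohort$schedule,
                        noise_scale = cohort$cohort$noise_scale,
                        seed = row$noise_seed)
    } else {
      img <- realize_scan_image(cohort, i, labels)
      stats::setNames(lapply(rois, extract_tac, image = img), names(rois))
    }
    list(subject = row$subject, scan = row$scan, group = row$group,
         pair_type = row$pair_type, interscan_days = row$interscan_days,
         input = cohort$cp, tacs = tacs)
  })
}
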