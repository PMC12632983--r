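#' ROI mask
#'
#' @param mask 3-D logical array.
#' @param name Region name.
#' @param voxel_size_mm Voxel edge lengths (mm).
#' @param threshold_used Map threshold that produced the mask, if any.
#' @export
roi_mask <- function(mask, name, voxel_size_mm, threshold_used = NA_real_) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  if (!any(mask)) stop("empty mask: ", name)
  structure(list(mask = mask, name = name,
                 voxel_size_mm = rep_len(voxel_size_mm, 3L),
                 volume_mL = sum(mask) * voxel_volume_mL(voxel_size_mm),
                 threshold_used = threshold_used),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("roi_mask '%s': %d voxels, %.3f mL\n",
              x$name, sum(x$mask), x$volume_mL))
  invisible(x)
}

#' Smoothed white-matter probability map
#'
#' Binarizes the WM label and smooths it with a Gaussian kernel of the
#' given FWHM (sigma = FWHM/2.3548 mm, converted to voxels per axis, zero
#' padding outside the volume). The result is a map in [0, 1] whose
#' high-value core lies in deep WM, far from gray matter.
#'
#' @param labels A `label_volume`.
#' @param wm_code Label code (or region name) of cerebral white matter.
#' @param fwhm_mm Smoothing kernel FWHM, mm (> 0).
#' @return Object of class `prob_volume` with fields `values`,
#'   `voxel_size_mm`, `fwhm_mm`.
#' @export
make_wm_map <- function(labels, wm_code = "cerebral_wm", fwhm_mm = 10) {
  stopifnot(inherits(labels, "label_volume"), fwhm_mm > 0)
  if (is.character(wm_code)) {
    if (!wm_code %in% names(labels$code_map)) stop("unknown region: ", wm_code)
    wm_code <- labels$code_map[[wm_code]]
  }
  ind <- labels$labels == wm_code
  if (!any(ind)) stop("wm_code ", wm_code, " absent from label volume")
  vals <- smooth_gaussian_3d(ind * 1, fwhm_mm, labels$voxel_size_mm)
  vals[vals < 0] <- 0
  vals[vals > 1] <- 1
  structure(list(values = vals, voxel_size_mm = labels$voxel_size_mm,
                 fwhm_mm = fwhm_mm),
            class = "prob_volume")
}

# Ordering used for volume thresholding: by decreasing map value, ties by
# lexicographic (linear array) voxel index.
.map_order <- function(values) {
  pos <- which(values > 0)
  pos[order(values[pos], pos, decreasing = c(TRUE, FALSE), method = "radix")]
}

#' Threshold a probability map to a target ROI volume
#'
#' Selects the highest-valued voxels of the map so that the achieved volume
#' is closest to `target_mL`. Equivalent to thresholding the map at the
#' value of the last included voxel; when several voxels share that value,
#' ties are broken by lexicographic voxel index so the target count is hit
#' exactly. The achieved volume is within half a voxel of the target
#' whenever enough positive voxels exist.
#'
#' @param wm_map A `prob_volume` from [make_wm_map()].
#' @param target_mL Target ROI volume, mL.
#' @param name Name for the resulting mask.
#' @return An [roi_mask()]; `threshold_used` records the map value of the
#'   last included voxel.
#' @export
threshold_to_volume <- function(wm_map, target_mL,
                                name = sprintf("FBWM_%gmL", target_mL)) {
  stopifnot(inherits(wm_map, "prob_volume"), target_mL > 0)
  vox_mL <- voxel_volume_mL(wm_map$voxel_size_mm)
  ord <- .map_order(wm_map$values)
  max_mL <- length(ord) * vox_mL
  k <- round(target_mL / vox_mL)
  if (k < 1) k <- 1L
  if (k > length(ord))
    stop(sprintf(
      "target volume %g mL unattainable: map supports at most %g mL",
      target_mL, max_mL))
  mask <- array(FALSE, dim(wm_map$values))
  mask[ord[seq_len(k)]] <- TRUE
  roi_mask(mask, name, wm_map$voxel_size_mm,
           threshold_used = wm_map$values[ord[k]])
}

#' Volume series of white-matter reference ROIs
#'
#' Builds the thresholded WM ROI series (default sizes 0.5, 1, 2, 5, 10,
#' 20, 45, 100, 200 mL) from a single smoothed WM map. All masks come from
#' one voxel ordering, so smaller ROIs are strictly nested inside larger
#' ones.
#'
#' @param labels A `label_volume`.
#' @param wm_code WM label code or region name.
#' @param fwhm_mm Smoothing FWHM, mm.
#' @param sizes_mL Strictly increasing target volumes, mL.
#' @return Named list of [roi_mask()] (names `FBWM_<size>mL`).
#' @export
make_fbwm_series <- function(labels, wm_code = "cerebral_wm", fwhm_mm = 10,
                             sizes_mL = c(0.5, 1, 2, 5, 10, 20, 45, 100, 200)) {
  stopifnot(all(diff(sizes_mL) > 0))
  wm_map <- make_wm_map(labels, wm_code, fwhm_mm)
  out <- lapply(sizes_mL, function(s) threshold_to_volume(wm_map, s))
  names(out) <- vapply(out, `[[`, character(1), "name")
  out
}

#' Default gray-matter merge map for the phantom
#'
#' In the phantom each evaluated gray-matter region is a single label, so
#' the merge map is one code per region; with a finer parcellation each
#' entry would list several member codes.
#'
#' @param labels A `label_volume`.
#' @export
default_gm_merge_map <- function(labels) {
  stats::setNames(lapply(GM_REGIONS, function(r) labels$code_map[[r]]),
                  GM_REGIONS)
}

#' Merge parcellation labels into named gray-matter ROIs
#'
#' @param labels A `label_volume`.
#' @param merge_map Named list: merged region name -> vector of member
#'   label codes present in `labels`.
#' @return Named list of [roi_mask()]; masks are disjoint whenever the
#'   member label sets are.
#' @export
merge_gm_rois <- function(labels, merge_map = default_gm_merge_map(labels)) {
  stopifnot(inherits(labels, "label_volume"), length(merge_map) > 0)
  present <- unique(as.vector(labels$labels))
  out <- lapply(names(merge_map), function(nm) {
    codes <- merge_map[[nm]]
    if (length(codes) == 0) stop("empty merge: ", nm)
    unknown <- setdiff(codes, present)
    if (length(unknown))
      stop("unknown code(s) in merge '", nm, "': ",
           paste(unknown, collapse = ", "))
    roi_mask(array(labels$labels %in% codes, dim(labels$labels)),
             nm, labels$voxel_size_mm)
  })
  stats::setNames(out, names(merge_map))
}

#' Extract the ROI-mean time-activity curve from a dynamic image
#'
#' @param image A `dynamic_image` (see [simulate_dynamic_pet()]).
#' @param roi An [roi_mask()] on the same grid.
#' @return A [tac()]: per frame, the unweighted mean of in-mask voxels.
#' @export
extract_tac <- function(image, roi) {
  stopifnot(inherits(image, "dynamic_image"), inherits(roi, "roi_mask"))
  if (!identical(dim(image$data)[1:3], dim(roi$mask)))
    stop("image and mask grids differ")
  if (!any(roi$mask)) stop("empty mask: ", roi$name)
  nf <- dim(image$data)[4]
  m <- matrix(image$data, ncol = nf)[as.vector(roi$mask), , drop = FALSE]
  tac(image$schedule, colMeans(m))
}
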