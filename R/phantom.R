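#' Regions evaluated as gray-matter targets
#'
#' The twelve gray-matter regions over which DVR test-retest variability is
#' averaged: six cortical sectors, two cingulate sectors, and four deep
#' structures. The substantia nigra and brainstem are modelled separately
#' (they are disease-effect regions, not part of the 12-region average).
#'
#' @export
GM_REGIONS <- c("frontal", "parietal", "occipital", "temporal",
                "anterior_cingulate", "posterior_cingulate",
                "putamen", "thalamus", "caudate",
                "hippocampus", "entorhinal", "amygdala")

#' Regions with reduced binding in the Parkinson's disease cohort
#' @export
PD_REGIONS <- c("substantia_nigra", "caudate", "brainstem")

.default_label_codes <- function() {
  c(cerebral_wm = 2L, ventricles = 4L,
    frontal = 10L, parietal = 11L, occipital = 12L, temporal = 13L,
    anterior_cingulate = 14L, posterior_cingulate = 15L,
    putamen = 16L, thalamus = 17L, caudate = 18L,
    hippocampus = 19L, entorhinal = 20L, amygdala = 21L,
    substantia_nigra = 30L, brainstem = 31L)
}

#' Specification of the digital brain phantom
#'
#' Describes a brain-like parcellation on a regular voxel grid. The
#' cerebral white matter (WM) is the shell between an outer ellipsoid and
#' an inner "ventricular" interior (CSF-like, near-zero uptake): a thin
#' (about 10 mm) WM sheet everywhere, except for a thick dorsal pocket -
#' the centrum semiovale - carved upward into the interior, where the
#' small 2 mL reference analogue sits far from gray matter. A cortical
#' gray-matter shell (six cortical + two cingulate sectors) surrounds the
#' outer ellipsoid; deep gray-matter nuclei (putamen, thalamus, caudate,
#' hippocampus, entorhinal, amygdala, substantia nigra) border the
#' ventricular interior or pierce the WM sheet, and a brainstem descends
#' through the open inferior pole.
#'
#' Because the sheet is thinner than the 10 mm map-smoothing kernel, only
#' the dorsal pocket produces high smoothed-map values: small thresholded
#' WM ROIs stay in the pocket, while growing ROIs are forced into the
#' sheet and toward cortex. That thickness structure is the mechanism
#' behind size-dependent spill-in bias of WM reference regions.
#'
#' Defaults: 90^3 grid of 2 mm isotropic voxels; geometry sized so the WM
#' compartment exceeds 250 mL after carving, keeping the largest (200 mL)
#' thresholded WM ROI constructible.
#'
#' @param grid_shape Integer vector of 3, voxels per axis.
#' @param voxel_size_mm Isotropic voxel edge length (mm).
#' @param wm_semiaxes_mm Semi-axes of the outer WM ellipsoid (mm).
#' @param ventricle_center_mm,ventricle_semiaxes_mm Inner (ventricular)
#'   ellipsoid, mm relative to the grid centre.
#' @param pocket_center_mm,pocket_semiaxes_mm Dorsal WM pocket carved out
#'   of the ventricular interior (the centrum semiovale analogue home).
#' @param shell_thickness_mm Cortical ribbon thickness (mm).
#' @param shell_cap_uz Unit-direction z below which the shell is open
#'   (no cortex at the inferior pole, where the brainstem exits).
#' @param deep_structures Named list; each element `list(center_mm,
#'   semiaxes_mm)` in mm relative to the grid centre.
#' @param cs_center_mm Centre of the 2 mL deep-WM reference analogue
#'   (default mid-way through the dorsal pocket).
#' @param cs_volume_mL Volume of the reference analogue sphere.
#' @param label_codes Named integer vector, region name -> label code.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(90L, 90L, 90L),
                         voxel_size_mm = 2,
                         wm_semiaxes_mm = c(50, 58, 44),
                         ventricle_center_mm = c(0, 0, 0),
                         ventricle_semiaxes_mm = c(40, 48, 34),
                         pocket_center_mm = c(0, -4, 30),
                         pocket_semiaxes_mm = c(16, 16, 14),
                         shell_thickness_mm = 8,
                         shell_cap_uz = -0.75,
                         deep_structures = NULL,
                         cs_center_mm = c(0, -4, 30),
                         cs_volume_mL = 2,
                         label_codes = .default_label_codes()) {
  if (is.null(deep_structures)) {
    deep_structures <- list(
      putamen          = list(center_mm = c(-34,   2,  -4), semiaxes_mm = rep(8, 3)),
      thalamus         = list(center_mm = c( 14, -12,  -8), semiaxes_mm = rep(9, 3)),
      caudate          = list(center_mm = c( 16,  14,  20), semiaxes_mm = rep(8, 3)),
      hippocampus      = list(center_mm = c( 30, -18, -16), semiaxes_mm = rep(7, 3)),
      entorhinal       = list(center_mm = c(-30, -16, -17), semiaxes_mm = rep(6, 3)),
      amygdala         = list(center_mm = c( 27,   8, -18), semiaxes_mm = rep(6, 3)),
      substantia_nigra = list(center_mm = c(  8, -28, -16), semiaxes_mm = rep(6.5, 3)),
      brainstem        = list(center_mm = c(  0, -12, -40), semiaxes_mm = c(9, 10, 16))
    )
  }
  spec <- structure(list(
    grid_shape = as.integer(grid_shape),
    voxel_size_mm = voxel_size_mm,
    wm_semiaxes_mm = wm_semiaxes_mm,
    ventricle_center_mm = ventricle_center_mm,
    ventricle_semiaxes_mm = ventricle_semiaxes_mm,
    pocket_center_mm = pocket_center_mm,
    pocket_semiaxes_mm = pocket_semiaxes_mm,
    shell_thickness_mm = shell_thickness_mm,
    shell_cap_uz = shell_cap_uz,
    deep_structures = deep_structures,
    cs_center_mm = cs_center_mm,
    cs_volume_mL = cs_volume_mL,
    label_codes = label_codes
  ), class = "phantom_spec")
  spec
}

# Voxel-centre coordinate arrays (mm, origin at grid centre).
.grid_coords <- function(grid_shape, voxel_size_mm) {
  ax <- lapply(grid_shape, function(n) (seq_len(n) - (n + 1) / 2) * voxel_size_mm)
  list(
    x = array(rep(ax[[1]], times = grid_shape[2] * grid_shape[3]), grid_shape),
    y = array(rep(rep(ax[[2]], each = grid_shape[1]), times = grid_shape[3]), grid_shape),
    z = array(rep(ax[[3]], each = grid_shape[1] * grid_shape[2]), grid_shape)
  )
}

.ellipsoid_mask <- function(co, center, semiaxes) {
  ((co$x - center[1]) / semiaxes[1])^2 +
    ((co$y - center[2]) / semiaxes[2])^2 +
    ((co$z - center[3]) / semiaxes[3])^2 <= 1
}

#' Build the phantom label volume
#'
#' Deterministically rasterizes a [phantom_spec()] into an integer label
#' volume. Deep structures are embedded (carved out of the WM and shell);
#' any overlap between two deep structures, or an empty named region, or a
#' WM compartment below 250 mL is a specification error naming the region.
#'
#' @param spec A [phantom_spec()].
#' @return A `label_volume`: integer 3-D array with attributes
#'   `voxel_size_mm` and `code_map`.
#' @export
build_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  co <- .grid_coords(spec$grid_shape, spec$voxel_size_mm)
  vox_mL <- spec$voxel_size_mm^3 / 1000

  deep <- lapply(spec$deep_structures, function(d)
    .ellipsoid_mask(co, d$center_mm, d$semiaxes_mm))
  for (nm in names(deep)) {
    if (!any(deep[[nm]])) stop("empty region: ", nm)
  }
  nms <- names(deep)
  if (length(nms) > 1) {
    for (i in seq_len(length(nms) - 1)) for (j in seq.int(i + 1, length(nms))) {
      if (any(deep[[i]] & deep[[j]]))
        stop("overlapping regions: ", nms[i], ", ", nms[j])
    }
  }
  any_deep <- Reduce(`|`, deep)

  a <- spec$wm_semiaxes_mm
  wm_ell <- .ellipsoid_mask(co, c(0, 0, 0), a)
  vent <- .ellipsoid_mask(co, spec$ventricle_center_mm,
                          spec$ventricle_semiaxes_mm) &
    !.ellipsoid_mask(co, spec$pocket_center_mm, spec$pocket_semiaxes_mm)
  outer_ell <- .ellipsoid_mask(co, c(0, 0, 0), a + spec$shell_thickness_mm)

  # unit direction from the grid centre, for shell sector rules
  rr <- sqrt(co$x^2 + co$y^2 + co$z^2)
  rr[rr == 0] <- 1
  ux <- co$x / rr; uy <- co$y / rr; uz <- co$z / rr

  shell <- outer_ell & !wm_ell & uz > spec$shell_cap_uz & !any_deep

  labels <- array(0L, spec$grid_shape)
  codes <- spec$label_codes

  # cortical shell sectors, first rule wins
  assign_shell <- function(cond, code) {
    sel <- shell & cond & labels == 0L
    labels[sel] <<- code
  }
  assign_shell(abs(ux) < 0.2 & uz > 0.15 & uy > 0.1,  codes[["anterior_cingulate"]])
  assign_shell(abs(ux) < 0.2 & uz > 0.15 & uy <= -0.1, codes[["posterior_cingulate"]])
  assign_shell(uy > 0.45,  codes[["frontal"]])
  assign_shell(uy < -0.45, codes[["occipital"]])
  assign_shell(uz > 0.25,  codes[["parietal"]])
  assign_shell(rep(TRUE, length(labels)), codes[["temporal"]])

  labels[wm_ell & !vent & !any_deep] <- codes[["cerebral_wm"]]
  labels[wm_ell & vent & !any_deep] <- codes[["ventricles"]]
  for (nm in names(deep)) labels[deep[[nm]]] <- codes[[nm]]

  for (nm in names(codes)) {
    if (!any(labels == codes[[nm]])) stop("empty region: ", nm)
  }
  wm_mL <- sum(labels == codes[["cerebral_wm"]]) * vox_mL
  if (wm_mL < 250)
    stop("WM compartment too small: ", round(wm_mL, 1),
         " mL < 250 mL (region: cerebral_wm)")

  label_volume(labels, spec$voxel_size_mm, codes)
}

#' Construct a label volume
#'
#' @param labels 3-D integer array of region codes (0 = background).
#' @param voxel_size_mm Voxel edge lengths (mm), length 1 or 3.
#' @param code_map Named integer vector mapping region names to codes; must
#'   cover every nonzero label present.
#' @export
label_volume <- function(labels, voxel_size_mm, code_map) {
  stopifnot(length(dim(labels)) == 3L, all(labels >= 0))
  present <- setdiff(unique(as.vector(labels)), 0L)
  missing <- setdiff(present, unname(code_map))
  if (length(missing))
    stop("labels present but not in code_map: ", paste(missing, collapse = ", "))
  structure(list(labels = labels,
                 voxel_size_mm = rep_len(voxel_size_mm, 3L),
                 code_map = code_map),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  cat("label_volume:", paste(dim(x$labels), collapse = " x "),
      "voxels,", paste(x$voxel_size_mm, collapse = "x"), "mm,",
      length(x$code_map), "regions\n")
  invisible(x)
}

#' Voxel volume in mL for a label volume or compatible object
#' @param voxel_size_mm Voxel edge lengths in mm (length 1 or 3).
#' @export
voxel_volume_mL <- function(voxel_size_mm) {
  prod(rep_len(voxel_size_mm, 3L)) / 1000
}

#' Region mask from a label volume
#' @param labels A `label_volume`.
#' @param region Region name (in `code_map`).
#' @export
region_mask <- function(labels, region) {
  stopifnot(inherits(labels, "label_volume"))
  if (!region %in% names(labels$code_map)) stop("unknown region: ", region)
  roi_mask(labels$labels == labels$code_map[[region]], region,
           labels$voxel_size_mm)
}

#' Deep white-matter small-reference analogue
#'
#' A fixed-volume sphere placed in deep WM, the phantom's stand-in for the
#' small (2 mL) centrum semiovale template reference. Restricted to voxels
#' labelled as cerebral WM.
#'
#' @param labels A `label_volume` built from `spec`.
#' @param spec The [phantom_spec()] used to build `labels`.
#' @return A `roi_mask` named `"CS2mL_analogue"`.
#' @export
cs_analogue_mask <- function(labels, spec) {
  stopifnot(inherits(labels, "label_volume"), inherits(spec, "phantom_spec"))
  r_mm <- (3 * spec$cs_volume_mL * 1000 / (4 * pi))^(1 / 3)
  co <- .grid_coords(spec$grid_shape, spec$voxel_size_mm)
  sph <- .ellipsoid_mask(co, spec$cs_center_mm, rep(r_mm, 3))
  m <- sph & labels$labels == spec$label_codes[["cerebral_wm"]]
  if (!any(m)) stop("empty region: CS2mL_analogue")
  roi_mask(m, "CS2mL_analogue", spec$voxel_size_mm)
}

#' Ground-truth one-tissue kinetics per region
#'
#' Per-region influx rate K1 (mL/cm^3/min) and efflux rate k2 (1/min), so
#' that VT_true = K1/k2 (mL/cm^3). Defaults emulate a high-uptake SV2A-like
#' tracer: white matter VT 4.3 (a realistic deep-WM reference value) and
#' gray-matter VT 2.9-4.9x higher; ventricles are CSF-like (VT 0.4).
#'
#' @param K1 Named numeric vector of influx rates; names are region names.
#' @param VT Named numeric vector of true distribution volumes; same names.
#' @return Object of class `kinetic_truth` with fields `K1`, `k2`, `VT`.
#' @export
kinetic_truth <- function(K1 = NULL, VT = NULL) {
  if (is.null(VT)) {
    VT <- c(cerebral_wm = 4.3, ventricles = 0.4,
            frontal = 20.0, parietal = 19.5, occipital = 18.0,
            temporal = 18.5, anterior_cingulate = 20.5,
            posterior_cingulate = 21.0, putamen = 20.0, thalamus = 17.0,
            caudate = 18.0, hippocampus = 15.0, entorhinal = 14.5,
            amygdala = 16.0, substantia_nigra = 15.0, brainstem = 12.5)
  }
  if (is.null(K1)) {
    K1 <- c(cerebral_wm = 0.13, ventricles = 0.02,
            frontal = 0.30, parietal = 0.30, occipital = 0.29,
            temporal = 0.29, anterior_cingulate = 0.31,
            posterior_cingulate = 0.31, putamen = 0.32, thalamus = 0.30,
            caudate = 0.28, hippocampus = 0.25, entorhinal = 0.24,
            amygdala = 0.26, substantia_nigra = 0.27, brainstem = 0.24)
    K1 <- K1[names(VT)]
  }
  stopifnot(identical(names(K1), names(VT)), all(K1 > 0), all(VT > 0))
  k2 <- K1 / VT
  wm_vt <- VT[["cerebral_wm"]]
  gm <- setdiff(names(VT), c("cerebral_wm", "ventricles"))
  if (any(VT[gm] <= wm_vt))
    stop("gray-matter VT must exceed white-matter VT: ",
         paste(gm[VT[gm] <= wm_vt], collapse = ", "))
  structure(list(K1 = K1, k2 = k2, VT = VT), class = "kinetic_truth")
}

#' @export
print.kinetic_truth <- function(x, ...) {
  cat("kinetic_truth:", length(x$K1), "regions; VT range",
      round(min(x$VT), 2), "-", round(max(x$VT), 2), "mL/cm^3\n")
  invisible(x)
}
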