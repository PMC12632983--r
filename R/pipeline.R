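#' Default pipeline configuration
#'
#' Nested parameter blocks for the end-to-end run: phantom geometry,
#' ground-truth kinetics, cohort design, ROI construction, and evaluation
#' settings. Any block accepts the arguments of the corresponding
#' constructor ([phantom_spec()], [cohort_spec()], ...).
#'
#' @param seed Master seed for the run.
#' @param out_dir Output directory.
#' @return Named list (a `RunConfig`).
#' @export
default_config <- function(seed = 1L, out_dir = "wmref_run") {
  list(
    seed = seed,
    out_dir = out_dir,
    method = "roi",
    phantom = list(),
    cohort = list(),
    roi = list(fwhm_mm = 10, sizes_mL = c(0.5, 1, 2, 5, 10, 20, 45, 100, 200)),
    evaluate = list(standard_reference = "CS2mL_analogue", bias_limit = 10)
  )
}

.known_config_keys <- c("seed", "out_dir", "method", "phantom", "cohort",
                        "roi", "evaluate")

#' Validate a pipeline configuration
#'
#' Checks every block against its invariants and reports all violations
#' at once.
#'
#' @param config Configuration list (see [default_config()]).
#' @return Character vector of error messages; length 0 when valid.
#' @export
validate_config <- function(config) {
  errs <- character()
  unknown <- setdiff(names(config), .known_config_keys)
  if (length(unknown))
    errs <- c(errs, paste("unknown config key(s):",
                          paste(unknown, collapse = ", ")))
  full <- utils::modifyList(default_config(), config)
  if (!is.numeric(full$seed) || length(full$seed) != 1)
    errs <- c(errs, "seed must be a single number")
  if (!full$method %in% c("roi", "image"))
    errs <- c(errs, "method must be 'roi' or 'image'")
  roi <- full$roi
  if (!is.null(roi$fwhm_mm) && roi$fwhm_mm <= 0)
    errs <- c(errs, "roi$fwhm_mm must be positive")
  if (!is.null(roi$sizes_mL) && any(diff(roi$sizes_mL) <= 0))
    errs <- c(errs, "roi$sizes_mL must be strictly increasing")
  ph <- tryCatch(do.call(phantom_spec, full$phantom),
                 error = function(e) conditionMessage(e))
  if (is.character(ph)) errs <- c(errs, paste("phantom:", ph))
  co <- tryCatch(do.call(cohort_spec, full$cohort),
                 error = function(e) conditionMessage(e))
  if (is.character(co)) errs <- c(errs, paste("cohort:", co))
  errs
}

#' Read a configuration from YAML
#' @param path YAML file.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  errs <- validate_config(cfg)
  if (length(errs)) stop("invalid config: ", paste(errs, collapse = "; "))
  cfg
}

#' Run the full pipeline
#'
#' simulate -> build ROIs -> fit VT -> DVR/TRV -> evaluate, writing every
#' stage table under `out_dir` plus a JSON evaluation report and a run
#' manifest (config hash, seed, package version, per-file checksums).
#' Identical config and seed give byte-identical numeric tables.
#'
#' @param config Configuration list; see [default_config()].
#' @return The run manifest (invisibly also written as JSON).
#' @export
run_pipeline <- function(config = default_config()) {
  errs <- validate_config(config)
  if (length(errs)) stop("invalid config: ", paste(errs, collapse = "; "))
  config <- utils::modifyList(default_config(), config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  put <- function(x, name) {
    p <- file.path(config$out_dir, name)
    write_table_tsv(x, p)
    files[[name]] <<- p
  }

  stage <- "phantom"
  res <- tryCatch({
    pspec <- do.call(phantom_spec, config$phantom)
    labels <- build_phantom(pspec)
    truth <- kinetic_truth()

    stage <- "make-rois"
    fbwm <- make_fbwm_series(labels, fwhm_mm = config$roi$fwhm_mm,
                             sizes_mL = config$roi$sizes_mL)
    gm <- merge_gm_rois(labels)
    rois <- c(fbwm,
              list(CS2mL_analogue = cs_analogue_mask(labels, pspec)),
              gm,
              list(substantia_nigra = region_mask(labels, "substantia_nigra"),
                   brainstem = region_mask(labels, "brainstem")))

    stage <- "simulate"
    cargs <- utils::modifyList(config$cohort, list(seed = config$seed))
    cspec <- do.call(cohort_spec, cargs)
    cohort <- simulate_cohort(pspec, truth, cspec)
    scans <- cohort_roi_tacs(cohort, rois, method = config$method,
                             labels = labels)

    stage <- "fit"
    vt <- compute_vt_table(scans)
    put(vt, "vt_table.tsv")

    stage <- "quantify"
    refs <- c(names(fbwm), "CS2mL_analogue")
    hs_vt <- vt[vt$group == "HS", ]
    trv_all <- list()
    for (rf in refs) {
      dvr <- compute_dvr(hs_vt, rf, targets = GM_REGIONS)
      trv_all[[rf]] <- trv_records(dvr, region_col = "target",
                                   value_col = "dvr",
                                   measure = paste0("DVR_", rf))
    }
    trv_vt <- trv_records(hs_vt[hs_vt$region %in% GM_REGIONS, ],
                          measure = "VT")
    trv <- do.call(rbind, c(trv_all, list(trv_vt)))
    put(trv, "trv_records.tsv")
    put(summarize_trv(trv), "trv_summary.tsv")
    gmavg <- gm_average_trv(trv)
    put(gmavg$per_subject, "trv_gm_average.tsv")
    put(gmavg$summary, "trv_gm_summary.tsv")

    stage <- "evaluate"
    vols <- vapply(rois[refs], `[[`, numeric(1), "volume_mL")
    bias <- reference_bias_table(vt[vt$group == "HS", ], refs,
                                 config$evaluate$standard_reference,
                                 volumes_mL = vols,
                                 bias_limit = config$evaluate$bias_limit)
    put(bias, "reference_bias.tsv")
    sds <- gmavg$summary
    sds <- sds[sds$pair_type == "longitudinal" | !"longitudinal" %in% sds$pair_type, ]
    trv_sds <- data.frame(reference = sub("^DVR_", "", sds$measure),
                          trv_sd = sds$sd_trv)
    sel <- select_reference(bias, trv_sds)
    put(sel$report, "reference_selection.tsv")

    regression <- NULL
    long <- gmavg$per_subject[gmavg$per_subject$pair_type == "longitudinal", ]
    sel_measure <- paste0("DVR_", if (is.na(sel$selected)) refs[1] else sel$selected)
    lsel <- long[long$measure == sel_measure, ]
    if (nrow(lsel) >= 3)
      regression <- interscan_regression(lsel$gm_trv, lsel$interscan_days)

    groups <- NULL
    if (sum(vt$group == "PD") >= 2) {
      cmp_refs <- unique(c(sel$selected, config$evaluate$standard_reference))
      cmp_refs <- cmp_refs[!is.na(cmp_refs)]
      groups <- do.call(rbind, lapply(cmp_refs, function(rf) {
        dvr <- compute_dvr(vt[vt$scan == 1, ], rf, targets = PD_REGIONS)
        do.call(rbind, lapply(intersect(PD_REGIONS, unique(dvr$target)),
          function(rg) {
            a <- dvr$dvr[dvr$target == rg & dvr$group == "HS"]
            b <- dvr$dvr[dvr$target == rg & dvr$group == "PD"]
            group_compare(a, b, region = rg, reference = rf)
          }))
      }))
      put(groups, "group_stats.tsv")
    }

    report <- list(selected_reference = sel$selected,
                   selection_note = sel$note,
                   interscan_regression = regression,
                   n_fit_failures = sum(!vt$converged))
    rp <- file.path(config$out_dir, "evaluation_report.json")
    jsonlite::write_json(report, rp, auto_unbox = TRUE, digits = NA,
                         null = "null")
    files[["evaluation_report.json"]] <- rp
    TRUE
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })

  cfg_path <- file.path(config$out_dir, "config.json")
  jsonlite::write_json(config, cfg_path, auto_unbox = TRUE, digits = NA)
  files[["config.json"]] <- cfg_path
  manifest <- list(
    config_hash = unname(tools::md5sum(cfg_path)),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("wmref")),
    files = as.list(vapply(files, function(p) unname(tools::md5sum(p)),
                           character(1))),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
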