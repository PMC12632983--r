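#' Write a volume to NIfTI-1
#'
#' Label volumes are stored as 32-bit integers, ROI masks as 8-bit
#' unsigned integers, dynamic images as 32-bit floats. Voxel sizes are
#' carried in the NIfTI pixdim; write-then-read is the identity on data
#' and geometry (up to float32 rounding for dynamic images).
#'
#' @param x A `label_volume`, `roi_mask` or `dynamic_image`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @export
write_volume <- function(x, path) {
  if (inherits(x, "label_volume")) {
    img <- RNifti::asNifti(x$labels)
    RNifti::pixdim(img) <- x$voxel_size_mm
    RNifti::writeNifti(img, path, datatype = "int32")
  } else if (inherits(x, "roi_mask")) {
    img <- RNifti::asNifti(x$mask * 1L)
    RNifti::pixdim(img) <- x$voxel_size_mm
    RNifti::writeNifti(img, path, datatype = "uint8")
  } else if (inherits(x, "dynamic_image")) {
    img <- RNifti::asNifti(x$data)
    RNifti::pixdim(img) <- c(x$voxel_size_mm, 1)
    RNifti::writeNifti(img, path, datatype = "float")
  } else stop("unsupported volume class: ", paste(class(x), collapse = "/"))
  invisible(path)
}

#' Read a volume from NIfTI-1
#'
#' @param path NIfTI file path.
#' @param as One of `"labels"`, `"mask"`, `"dynamic"`.
#' @param code_map Region code map (labels only).
#' @param schedule Frame schedule (dynamic only); its length must match
#'   the 4th dimension.
#' @param name Mask name (mask only).
#' @export
read_volume <- function(path, as = c("labels", "mask", "dynamic"),
                        code_map = NULL, schedule = NULL, name = "mask") {
  as <- match.arg(as)
  img <- RNifti::readNifti(path)
  vs <- RNifti::pixdim(img)
  arr <- array(as.vector(img), dim(img))   # plain array, no NIfTI attributes
  if (as == "dynamic") {
    if (length(dim(arr)) != 4L) stop("expected a 4-D image: ", path)
    if (is.null(schedule)) stop("a frame schedule is required")
    dynamic_image(arr, schedule, vs[1:3])
  } else {
    if (length(dim(arr)) != 3L) stop("expected a 3-D volume: ", path)
    if (as == "labels") {
      if (is.null(code_map)) stop("a code_map is required for labels")
      label_volume(array(as.integer(round(arr)), dim(arr)), vs[1:3], code_map)
    } else {
      roi_mask(arr != 0, name, vs[1:3])
    }
  }
}

#' Write a scan to disk (image + sidecars)
#'
#' NIfTI 4-D volume plus TSV frame schedule, TSV input function and JSON
#' metadata, the on-disk exchange format of the pipeline.
#'
#' @param image A [dynamic_image()].
#' @param cp The scan's [input_function()].
#' @param meta Named list of scan metadata (group, subject, scan, seed...).
#' @param prefix Output path prefix (directory + basename).
#' @return Named vector of the four file paths.
#' @export
write_scan <- function(image, cp, meta, prefix) {
  paths <- c(image = paste0(prefix, ".nii.gz"),
             schedule = paste0(prefix, "_frames.tsv"),
             input = paste0(prefix, "_input.tsv"),
             meta = paste0(prefix, ".json"))
  write_volume(image, paths[["image"]])
  write_schedule_tsv(image$schedule, paths[["schedule"]])
  write_input_tsv(cp, paths[["input"]])
  jsonlite::write_json(meta, paths[["meta"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Write a result table as TSV
#' @param x data.frame.
#' @param path Output path.
#' @export
write_table_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
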