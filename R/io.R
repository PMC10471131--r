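# File formats: NIfTI image stacks with JSON timing sidecars, cohort CSV,
# and YAML pipeline configuration. Maps are written as float32 NIfTI with
# the pixel spacing in the header and the units recorded in the sidecar.

#' Write an image stack (or map) as NIfTI with a JSON sidecar
#'
#' The sidecar records per-frame inversion times (`ti_ms`) or frame times
#' (`time_s`), the units, and any extra metadata; image data are written as
#' float32.
#'
#' @param data 2-D matrix or 3-D array.
#' @param path Output `.nii` / `.nii.gz` path; the sidecar replaces the
#'   extension with `.json`.
#' @param pixel_spacing Pixel size in mm.
#' @param ti_ms,time_s Optional per-frame timing vectors (one of them, with
#'   length equal to the frame count).
#' @param units Unit string stored in the sidecar (e.g. "ms", "fraction",
#'   "ml/min/g").
#' @param extra Named list merged into the sidecar.
#' @return Invisibly, `c(image = path, sidecar = sidecar_path)`.
#' @export
write_image_series <- function(data, path, pixel_spacing = 1.0,
                               ti_ms = NULL, time_s = NULL, units = "a.u.",
                               extra = list()) {
  if (inherits(data, "cmr_map")) {
    units <- data$units
    data <- data$values
  }
  stopifnot(is.numeric(data))
  arr <- if (is.matrix(data)) array(data, dim = c(dim(data), 1L)) else data
  n_frames <- dim(arr)[3]
  for (tv in list(ti_ms, time_s)) {
    if (!is.null(tv) && length(tv) != n_frames)
      stop_cfg("timing vector length (", length(tv),
               ") does not match frame count (", n_frames, ")")
  }
  img <- RNifti::asNifti(arr, datatype = "float", internal = FALSE)
  attr(img, "pixdim") <- c(pixel_spacing, pixel_spacing, 1)
  RNifti::writeNifti(img, path)
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  meta <- c(list(n_frames = n_frames, pixel_spacing_mm = pixel_spacing,
                 units = units),
            if (!is.null(ti_ms)) list(ti_ms = ti_ms),
            if (!is.null(time_s)) list(time_s = time_s),
            extra)
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(image = path, sidecar = sidecar))
}

#' Read an image stack and its timing metadata
#'
#' Reads a NIfTI volume plus its JSON sidecar; frames are reordered by
#' inversion time / frame time when a timing vector is present. Perfusion
#' frame times must form a uniform, strictly increasing grid.
#'
#' @param path NIfTI path; the sidecar is looked up next to it.
#' @return List with `stack` (rows x cols x frames array), `ti_ms` or
#'   `time_s` (when present, sorted), `units`, `pixel_spacing_mm`, and the
#'   raw sidecar `meta`.
#' @export
read_image_series <- function(path) {
  if (!file.exists(path)) stop_cfg("no such image: ", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 2L) arr <- array(arr, dim = c(dim(arr), 1L))
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  if (!file.exists(sidecar))
    stop_cfg("missing timing sidecar: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  n_frames <- dim(arr)[3]
  out <- list(stack = arr, units = meta$units %||% "a.u.",
              pixel_spacing_mm = meta$pixel_spacing_mm %||% 1, meta = meta)
  for (field in c("ti_ms", "time_s")) {
    tv <- meta[[field]]
    if (is.null(tv)) next
    if (length(tv) != n_frames)
      stop_cfg("sidecar lists ", length(tv), " frames but image has ", n_frames)
    ord <- order(tv)
    out$stack <- arr[, , ord, drop = FALSE]
    out[[field]] <- tv[ord]
    if (field == "time_s") {
      dts <- diff(out$time_s)
      if (any(dts <= 0)) stop_cfg("frame times must be strictly increasing")
      if (max(dts) - min(dts) > 1e-6 * stats::median(dts))
        stop_cfg("perfusion frame times must form a uniform grid")
    }
  }
  out
}

#' Write / read a cohort table as CSV
#'
#' Comma-separated, UTF-8, header row, '.' decimal. Hematocrit is stored as
#' a fraction; values above 1 on read are interpreted as percent and divided
#' by 100 (with a message), matching the percent convention of printed
#' cohort tables.
#'
#' @param cohort Cohort tibble (schema of [generate_cohort()]).
#' @param path CSV path.
#' @export
write_cohort_csv <- function(cohort, path) {
  readr::write_csv(cohort, path)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop_cfg("no such cohort file: ", path)
  cohort <- readr::read_csv(path, show_col_types = FALSE)
  if ("hct" %in% names(cohort) && any(cohort$hct > 1, na.rm = TRUE)) {
    inform("hct column read as percent; converting to fraction")
    cohort$hct <- cohort$hct / 100
  }
  cohort
}

#' Read a pipeline configuration from YAML
#'
#' Validates the fields used by [run_pipeline()]: seeds must be integers,
#' doses positive, and referenced files existing.
#'
#' @param path YAML file.
#' @return Config list (class `cmr_config`).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_cfg("no such config: ", path)
  cfg <- yaml::read_yaml(path)
  validate_config(cfg)
}

#' @rdname read_config
#' @param cfg A config list built in code.
#' @export
validate_config <- function(cfg) {
  stopifnot(is.list(cfg))
  if (!is.null(cfg$seed) && cfg$seed != as.integer(cfg$seed))
    stop_cfg("seed must be an integer")
  for (d in c("dose_low", "dose_high")) {
    if (!is.null(cfg[[d]]) && cfg[[d]] <= 0) stop_cfg(d, " must be positive")
  }
  for (f in cfg$files %||% list()) {
    if (!file.exists(f)) stop_cfg("referenced file does not exist: ", f)
  }
  structure(cfg, class = c("cmr_config", "list"))
}
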