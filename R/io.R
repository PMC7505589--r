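#' Read and write two-column physiological traces
#'
#' Traces travel as tab-delimited text with a header row; the first column
#' is time in seconds and the remaining columns carry the channels (value,
#' or po2/pco2 for a gas trace).
#'
#' @param path File path.
#' @return [read_trace()] returns a tibble.
#' @export
read_trace <- function(path) {
  as_tibble(utils::read.table(path, header = TRUE, sep = "\t"))
}

#' @rdname read_trace
#' @param x Tibble to write.
#' @export
write_trace <- function(x, path) {
  utils::write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write 4D volumes and parcellations as NIfTI-1
#'
#' @param vol A [volume_series()] (or, for [write_parcellation()], a
#'   [parcellation()]).
#' @param path Output path (`.nii` or `.nii.gz`).
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "volume_series"))
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- c(vol$voxel_dims_mm, vol$tr_s)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  volume_series(array(as.numeric(img), dim(img)),
                tr_s = pd[4], voxel_dims_mm = pd[1:3])
}

#' @rdname write_volume
#' @param parc A [parcellation()].
#' @export
write_parcellation <- function(parc, path) {
  stopifnot(inherits(parc, "parcellation"))
  RNifti::writeNifti(RNifti::asNifti(parc$labels + 0), path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_parcellation <- function(path) {
  img <- RNifti::readNifti(path)
  parcellation(array(as.integer(round(as.numeric(img))), dim(img)))
}

#' Read a pipeline run configuration from YAML or JSON
#'
#' The file holds the arguments of [tcd_config()] or [mri_config()]; unknown
#' keys are rejected by the constructor.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @param kind `"tcd"` or `"mri"`.
#' @return A validated config list.
#' @export
read_run_config <- function(path, kind = c("tcd", "mri")) {
  kind <- match.arg(kind)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    abort("config must be YAML or JSON")
  }
  do.call(if (kind == "tcd") tcd_config else mri_config, raw)
}

#' Shipped study summary tables
#'
#' `study_demographics()` returns the demographic and session-participation
#' table of the 22-subject resting-state TCD/MRI gas-exchange study the
#' package's defaults are modelled on; `study_rge_summary()` returns the
#' per-subject session means and SDs of the end-tidal pressures, the
#' within-breath excursions and the exchange ratio bER. Both are read from
#' plain-text tables installed with the package and are used for worked
#' examples and consistency checks (for a stationary record the mean bER
#' must match the ratio of the mean excursions).
#'
#' @return A tibble.
#' @export
study_demographics <- function() {
  read_trace(system.file("extdata", "subject_demographics.tsv",
                         package = "bercouple", mustWork = TRUE))
}

#' @rdname study_demographics
#' @export
study_rge_summary <- function() {
  read_trace(system.file("extdata", "rge_session_summary.tsv",
                         package = "bercouple", mustWork = TRUE))
}
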