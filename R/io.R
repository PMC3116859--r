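#' Write the outputs of a run to a directory
#'
#' Writes the per-generation time series (`series.csv`), the final lattice
#' snapshot (`snapshot.csv`: row, col, e1, e2, k, conformation), the final
#' enzyme-activity histogram (`histogram.csv`, long format) and a JSON
#' metadata sidecar (`metadata.json`: full parameter set, class regions, seed
#' and elapsed time).
#'
#' @param run An `mcrs_run`.
#' @param out_dir Output directory, created if missing.
#' @param bins Histogram bins per axis.
#' @return `out_dir`, invisibly.
#' @export
write_run <- function(run, out_dir, bins = 20) {
  stopifnot(inherits(run, "mcrs_run"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(run$series, file.path(out_dir, "series.csv"))
  readr::write_csv(tibble::as_tibble(run$final),
                   file.path(out_dir, "snapshot.csv"))
  readr::write_csv(phenotype_histogram(run$final, bins = bins),
                   file.path(out_dir, "histogram.csv"))
  meta <- list(
    package = "mcrs",
    version = as.character(utils::packageVersion("mcrs")),
    params = unclass(run$params),
    regions = unclass(run$regions),
    elapsed_seconds = run$elapsed
  )
  jsonlite::write_json(meta, file.path(out_dir, "metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' Read a lattice snapshot back into a lattice object
#'
#' @param path A `snapshot.csv` written by [write_run()].
#' @param params The [mcrs_params()] of the run (e.g. rebuilt from the
#'   metadata sidecar).
#' @return An `mcrs_lattice`.
#' @export
read_snapshot <- function(path, params) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  mcrs_lattice(params, df)
}

#' Rebuild a parameter object from a metadata sidecar
#'
#' @param path A `metadata.json` written by [write_run()].
#' @return An [mcrs_params()] object.
#' @export
read_params <- function(path) {
  meta <- jsonlite::read_json(path, simplifyVector = TRUE)
  fields <- meta$params
  fields$metabolic_neighbourhood <- NULL
  do.call(mcrs_params, fields)
}
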