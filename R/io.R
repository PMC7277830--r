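#' Write a registry bundle to delimited text files
#'
#' Each table is written as a comma-separated UTF-8 file with a header row
#' and ISO-8601 dates; a `manifest.json` records the file list, the seed and
#' a hash of the generating configuration.
#'
#' @param bundle A `cohortair_bundle` from [generate_cohort()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the manifest as a list.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "cohortair_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tables <- c("births", "episodes", "blocks", "concentrations", "monitors",
              "hospital", "growth_table", "truth")
  paths <- stats::setNames(file.path(dir, paste0(tables, ".csv")), tables)
  for (t in tables) {
    utils::write.csv(bundle[[t]], paths[[t]], row.names = FALSE,
                     fileEncoding = "UTF-8", na = "")
  }
  manifest <- list(
    tables = as.list(paths),
    seed = bundle$config$seed,
    config_hash = config_hash(unclass(bundle$config)),
    n_rows = lapply(bundle[tables], nrow)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Read a registry bundle written by [write_bundle()]
#'
#' Also accepts real registry extracts laid out with the same schema and
#' file names.
#'
#' @param dir Directory containing the CSV tables and `manifest.json`.
#' @return A `cohortair_bundle` list (without the generating config).
#' @export
read_bundle <- function(dir) {
  date_cols <- list(
    births = c("delivery_date", "lmp_date"),
    episodes = c("start_date", "end_date"),
    monitors = "date",
    hospital = c("admission_date", "discharge_date")
  )
  tables <- c("births", "episodes", "blocks", "concentrations", "monitors",
              "hospital", "growth_table", "truth")
  out <- list()
  for (t in tables) {
    path <- file.path(dir, paste0(t, ".csv"))
    if (!file.exists(path)) next
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
    df[df == ""] <- NA
    for (dc in date_cols[[t]]) df[[dc]] <- as.Date(df[[dc]])
    if (t == "hospital" && "diagnosis_codes" %in% names(df))
      df$diagnosis_codes <- as.character(df$diagnosis_codes)
    out[[t]] <- tibble::as_tibble(df)
  }
  class(out) <- "cohortair_bundle"
  out
}
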