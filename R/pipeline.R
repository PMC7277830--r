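#' Pipeline run configuration
#'
#' A single object that drives [run_pipeline()] end to end. Either a
#' synthetic-generator configuration or a directory of input tables (schema
#' of [write_bundle()]) must be supplied. All analytic conventions —
#' coverage tolerance, back-extrapolation mode and years, monitor-gap
#' interpolation limit, percentile scope — are configuration keys so that
#' sensitivity analyses are a one-line change.
#'
#' @param synth A [synth_config()], or `NULL` when reading from `input_dir`.
#' @param input_dir Directory with input tables, or `NULL`.
#' @param pollutants Pollutants to analyse (default: those configured /
#'   present).
#' @param backextrapolate Compute back-extrapolated exposures (default TRUE).
#' @param backextrap_years Delivery years eligible for back-extrapolation.
#' @param backextrap_mode `"daily_address"` or `"constant_weights"`.
#' @param tolerance_days Residence-coverage tolerance in days.
#' @param max_gap_days Monitor-gap interpolation limit in days.
#' @param lur_period LUR campaign period (Date pair), default calendar 2010.
#' @param percentile_scope `"city"` or `"pooled"` for the high-exposure
#'   threshold.
#' @param year_range Delivery-year selection range.
#' @param output_dir Where stage outputs and the manifest are written.
#' @return A validated `cohortair_run_config` list.
#' @export
run_config <- function(synth = NULL, input_dir = NULL, pollutants = NULL,
                       backextrapolate = TRUE,
                       backextrap_years = c(2008L, 2013L),
                       backextrap_mode = c("daily_address",
                                           "constant_weights"),
                       tolerance_days = 0, max_gap_days = 7,
                       lur_period = NULL,
                       percentile_scope = c("city", "pooled"),
                       year_range = NULL, output_dir = tempfile("cohortair_")) {
  backextrap_mode <- match.arg(backextrap_mode)
  percentile_scope <- match.arg(percentile_scope)
  if (is.null(synth) && is.null(input_dir))
    stop("invalid configuration: one of `synth` or `input_dir` is required",
         call. = FALSE)
  if (!is.null(input_dir) && !dir.exists(input_dir))
    stop(sprintf("invalid configuration: `input_dir` '%s' does not exist",
                 input_dir), call. = FALSE)
  supported <- c("PM10", "PM2.5", "PM2.5-10", "NO2", "NOx")
  if (!is.null(pollutants))
    .assert_config(all(pollutants %in% supported), "pollutants",
                   sprintf("must be a subset of {%s}",
                           paste(supported, collapse = ", ")))
  if (!is.null(synth)) {
    stopifnot(inherits(synth, "cohortair_synth_config"))
    if (is.null(pollutants)) pollutants <- synth$pollutants
    if (is.null(year_range)) year_range <- synth$year_range
  }
  structure(
    list(synth = synth, input_dir = input_dir, pollutants = pollutants,
         backextrapolate = backextrapolate,
         backextrap_years = as.integer(backextrap_years),
         backextrap_mode = backextrap_mode,
         tolerance_days = tolerance_days, max_gap_days = max_gap_days,
         lur_period = lur_period, percentile_scope = percentile_scope,
         year_range = year_range, output_dir = output_dir),
    class = "cohortair_run_config"
  )
}

#' Run the full pipeline
#'
#' generate/read -> demographic selection -> selection cascade + audit ->
#' deprivation index -> exposure profiles -> outcomes -> descriptives.
#' Stage outputs are written as CSV under `config$output_dir` and a run
#' manifest (configuration hash, seed, per-stage row counts, the audit)
#' is written as `run_manifest.json`. Re-running with an identical
#' configuration reproduces identical outputs.
#'
#' @param config A [run_config()].
#' @param write Write stage outputs to disk (default TRUE).
#' @return A list with all stage results (`bundle`, `cohort`, `audit`,
#'   `audit_years`, `deprivation`, `profiles`, `outcomes`,
#'   `exposure_by_city`, `categoricals`, `crosstabs`, `season_summary`,
#'   `manifest`).
#' @export
run_pipeline <- function(config, write = TRUE) {
  stopifnot(inherits(config, "cohortair_run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage `%s` failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  bundle <- stage("inputs", {
    if (!is.null(config$synth)) generate_cohort(config$synth)
    else read_bundle(config$input_dir)
  })
  pollutants <- config$pollutants
  if (is.null(pollutants)) pollutants <- unique(bundle$concentrations$pollutant)

  sel <- stage("select_initial",
               select_initial(bundle$births, config$year_range))
  casc <- stage("selection_cascade",
                apply_cascade(sel$selected, bundle$episodes,
                              bundle$concentrations, pollutants,
                              config$tolerance_days))
  depr <- stage("deprivation_index", deprivation_index(bundle$blocks))
  cohort <- stage("link_deprivation",
                  link_deprivation(casc$analysed, bundle$episodes, depr))
  profiles <- stage("exposure_profiles", exposure_profiles(
    cohort, bundle$episodes, bundle$concentrations, bundle$monitors,
    pollutants, lur_period = config$lur_period,
    max_gap_days = config$max_gap_days, mode = config$backextrap_mode,
    backextrap_years = if (config$backextrapolate) config$backextrap_years
                       else c(0L, 0L)))
  outc <- stage("outcomes", derive_outcomes(cohort, bundle$hospital,
                                            bundle$growth_table))
  expo_city <- stage("exposure_summary", exposure_summary(profiles))
  cats <- stage("categorical_summaries", dplyr::bind_rows(lapply(
    c("education", "occupation", "marital_status", "citizenship", "parity",
      "delivery_type", "infant_sex"),
    function(v) summarize_categorical(cohort, v))))
  xt <- stage("high_exposure_crosstabs", dplyr::bind_rows(lapply(
    pollutants, function(p) dplyr::bind_rows(lapply(
      c("education", "occupation_binary", "citizenship",
        "deprivation_quintile"),
      function(s) high_exposure_crosstab(cohort, profiles, p, s,
                                         config$percentile_scope))))))
  seas <- stage("season_summary", exposure_season_summary(profiles))

  manifest <- list(
    config_hash = config_hash(list(
      synth = if (!is.null(config$synth)) unclass(config$synth),
      input_dir = config$input_dir,
      pollutants = pollutants, backextrapolate = config$backextrapolate,
      backextrap_years = config$backextrap_years,
      backextrap_mode = config$backextrap_mode,
      tolerance_days = config$tolerance_days,
      max_gap_days = config$max_gap_days,
      percentile_scope = config$percentile_scope,
      year_range = config$year_range)),
    seed = if (!is.null(config$synth)) config$synth$seed,
    n_rows = list(births = nrow(bundle$births),
                  selected = nrow(sel$selected),
                  analysed = nrow(cohort),
                  profiles = nrow(profiles),
                  outcomes = nrow(outc)),
    audit = casc$audit)

  res <- list(bundle = bundle, cohort = cohort, audit = casc$audit,
              audit_years = casc$audit_years, deprivation = depr,
              profiles = profiles, outcomes = outc,
              exposure_by_city = expo_city, categoricals = cats,
              crosstabs = xt, season_summary = seas, manifest = manifest)
  if (write) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(x, f) utils::write.csv(
      x, file.path(config$output_dir, f), row.names = FALSE, na = "")
    wr(cohort, "analysed_cohort.csv")
    wr(casc$audit, "selection_audit.csv")
    wr(casc$audit_years, "analysed_by_year.csv")
    wr(depr, "deprivation_index.csv")
    wr(profiles, "exposure_profiles.csv")
    wr(outc, "outcomes.csv")
    wr(expo_city, "exposure_by_city.csv")
    wr(cats, "categorical_summaries.csv")
    wr(xt, "high_exposure_crosstabs.csv")
    wr(seas, "season_summary.csv")
    jsonlite::write_json(manifest, file.path(config$output_dir,
                                             "run_manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         dataframe = "columns")
    writeLines(format_audit(casc$audit),
               file.path(config$output_dir, "selection_audit.txt"))
  }
  res
}
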