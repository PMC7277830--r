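#' City specification for the synthetic registry generator
#'
#' @param name City name (unique within a configuration).
#' @param n_births_per_year Number of deliveries generated per calendar year.
#' @param n_census_blocks Number of census blocks in the city.
#' @param deprivation_pollution_correlation Named numeric vector in `[-1, 1]`,
#'   one entry per pollutant: the latent correlation between a census block's
#'   deprivation level and the modelled annual concentration at addresses in
#'   that block. Positive means more deprived blocks are more polluted. At
#'   `+/-1` the address concentration is a deterministic monotone function of
#'   the block's deprivation level.
#' @return A `cohortair_city_spec` list.
#' @export
city_spec <- function(name,
                      n_births_per_year = 1000,
                      n_census_blocks = 80,
                      deprivation_pollution_correlation = c(
                        PM10 = 0.5, PM2.5 = 0.3, NO2 = -0.4
                      )) {
  .assert_config(is.character(name) && length(name) == 1L && nzchar(name),
                 "name", "must be a non-empty string")
  .assert_config(length(n_births_per_year) == 1L && n_births_per_year > 0,
                 "n_births_per_year", "must be > 0")
  .assert_config(length(n_census_blocks) == 1L && n_census_blocks >= 2,
                 "n_census_blocks", "must be >= 2")
  rho <- deprivation_pollution_correlation
  .assert_config(is.numeric(rho) && !is.null(names(rho)) &&
                   all(rho >= -1 & rho <= 1),
                 "deprivation_pollution_correlation",
                 "must be a named numeric vector with values in [-1, 1]")
  structure(
    list(name = name,
         n_births_per_year = as.integer(n_births_per_year),
         n_census_blocks = as.integer(n_census_blocks),
         deprivation_pollution_correlation = rho),
    class = "cohortair_city_spec"
  )
}

#' Daily background-monitor model for one pollutant
#'
#' The generated daily series is
#' `baseline * (1 + amplitude * cos(2*pi*(doy - peak_doy)/365.25)) *
#'  (1 - decline)^(year - first_year) + noise`, truncated at zero. The cosine
#' peaks at `peak_doy` (early January by default), giving the winter maximum
#' seen in urban Italian PM and NO2 series; `decline` is the slow year-on-year
#' proportional decrease in concentrations.
#'
#' @param baseline Annual-mean level in ug/m3 in the first year.
#' @param amplitude Relative seasonal amplitude (0 = flat).
#' @param decline Annual proportional decline in `[0, 1)`.
#' @param noise_sd Standard deviation of additive daily noise (ug/m3).
#' @param peak_doy Day of year at which the seasonal cycle peaks.
#' @return A `cohortair_monitor_spec` list.
#' @export
monitor_spec <- function(baseline = 40, amplitude = 0.35, decline = 0.03,
                         noise_sd = 4, peak_doy = 1) {
  .assert_config(baseline >= 0, "baseline", "must be >= 0")
  .assert_config(amplitude >= 0, "amplitude", "must be >= 0")
  .assert_config(decline >= 0 && decline < 1, "decline", "must be in [0, 1)")
  .assert_config(noise_sd >= 0, "noise_sd", "must be >= 0")
  structure(
    list(baseline = baseline, amplitude = amplitude, decline = decline,
         noise_sd = noise_sd, peak_doy = peak_doy),
    class = "cohortair_monitor_spec"
  )
}

#' Configuration for the synthetic registry generator
#'
#' Bundles every tunable of [generate_cohort()]. Rates are fractions of
#' mothers planted into each linkage-failure class; they are drawn mutually
#' exclusively so the ground-truth labels in the generated bundle match the
#' selection audit exactly.
#'
#' @param seed Integer seed; identical seed + configuration reproduces the
#'   bundle bit-for-bit.
#' @param cities List of [city_spec()] objects.
#' @param year_range Inclusive calendar-year range of deliveries.
#' @param pollutants Character vector of pollutants to model; subset of
#'   `PM10, PM2.5, PM2.5-10, NO2, NOx`.
#' @param mobility_rate Fraction of mothers with one residential move during
#'   pregnancy.
#' @param out_of_city_rate Fraction of mothers with a residence gap outside
#'   the city during pregnancy (fails whole-pregnancy coverage).
#' @param geocoding_missing_rate Fraction with no linkable residence episodes.
#' @param exposure_missing_rate Fraction whose address lacks a modelled
#'   concentration for one pollutant.
#' @param malformation_rate Fraction of births flagged with a congenital
#'   malformation.
#' @param outcome_missing_rate Fraction missing one of the outcome fields
#'   (birthweight, infant sex or parity).
#' @param preterm_rate Target fraction of births before 37 completed weeks.
#' @param missingness Named list of per-field missing probabilities for the
#'   socio-demographic covariates (`education`, `occupation`,
#'   `marital_status`, `citizenship`). Per-city overrides are supported as a
#'   nested named list, e.g. `list(education = c(default = 0.015,
#'   "Turin" = 0.05))`.
#' @param monitor Named list of [monitor_spec()] per pollutant.
#' @param hospitalization_rate Fraction of mothers with a hospital admission
#'   during pregnancy.
#' @param hypertension_rate Fraction of admitted mothers whose discharge
#'   carries a hypertensive-disorder diagnosis (ICD-9 642.x).
#' @return A validated `cohortair_synth_config` list.
#' @export
synth_config <- function(seed = 1L,
                         cities = list(city_spec("Alpha")),
                         year_range = c(2007L, 2013L),
                         pollutants = c("PM10", "PM2.5", "NO2"),
                         mobility_rate = 0.15,
                         out_of_city_rate = 0.01,
                         geocoding_missing_rate = 0.025,
                         exposure_missing_rate = 0.019,
                         malformation_rate = 0.015,
                         outcome_missing_rate = 0.001,
                         preterm_rate = 0.06,
                         missingness = list(education = 0.015,
                                            occupation = 0.01,
                                            marital_status = 0.005,
                                            citizenship = 0.005),
                         monitor = NULL,
                         hospitalization_rate = 0.08,
                         hypertension_rate = 0.03) {
  .assert_config(length(seed) == 1L && is.finite(seed), "seed",
                 "must be a single integer")
  .assert_config(is.list(cities) && length(cities) >= 1L &&
                   all(vapply(cities, inherits, TRUE, "cohortair_city_spec")),
                 "cities", "must be a non-empty list of city_spec()")
  nm <- vapply(cities, `[[`, "", "name")
  .assert_config(!anyDuplicated(nm), "cities", "must have unique names")
  .assert_config(length(year_range) == 2L && year_range[1] <= year_range[2],
                 "year_range", "must be an increasing pair of years")
  supported <- c("PM10", "PM2.5", "PM2.5-10", "NO2", "NOx")
  .assert_config(all(pollutants %in% supported), "pollutants",
                 sprintf("must be a subset of {%s}",
                         paste(supported, collapse = ", ")))
  for (f in c("mobility_rate", "out_of_city_rate", "geocoding_missing_rate",
              "exposure_missing_rate", "malformation_rate",
              "outcome_missing_rate", "preterm_rate",
              "hospitalization_rate", "hypertension_rate")) {
    v <- get(f)
    .assert_config(length(v) == 1L && v >= 0 && v <= 1, f,
                   "must be a probability in [0, 1]")
  }
  .assert_config(sum(out_of_city_rate, geocoding_missing_rate,
                     exposure_missing_rate, malformation_rate,
                     outcome_missing_rate) <= 1,
                 "out_of_city_rate",
                 "and the other failure rates must sum to <= 1")
  for (f in names(missingness)) {
    v <- unlist(missingness[[f]])
    .assert_config(all(v >= 0 & v <= 1), paste0("missingness$", f),
                   "must be probabilities in [0, 1]")
  }
  if (is.null(monitor)) {
    defaults <- list(
      "PM10"    = monitor_spec(40, 0.35, 0.03, 4),
      "PM2.5"   = monitor_spec(22, 0.40, 0.03, 3),
      "PM2.5-10" = monitor_spec(16, 0.25, 0.02, 2.5),
      "NO2"     = monitor_spec(45, 0.30, 0.03, 5),
      "NOx"     = monitor_spec(80, 0.30, 0.03, 9)
    )
    monitor <- defaults[pollutants]
  }
  .assert_config(all(pollutants %in% names(monitor)), "monitor",
                 "must provide a monitor_spec for every pollutant")
  for (cs in cities) {
    .assert_config(all(pollutants %in%
                         names(cs$deprivation_pollution_correlation)),
                   "deprivation_pollution_correlation",
                   sprintf("for city '%s' must cover every pollutant", cs$name))
  }
  structure(
    list(seed = as.integer(seed), cities = cities,
         year_range = as.integer(year_range), pollutants = pollutants,
         mobility_rate = mobility_rate, out_of_city_rate = out_of_city_rate,
         geocoding_missing_rate = geocoding_missing_rate,
         exposure_missing_rate = exposure_missing_rate,
         malformation_rate = malformation_rate,
         outcome_missing_rate = outcome_missing_rate,
         preterm_rate = preterm_rate, missingness = missingness,
         monitor = monitor, hospitalization_rate = hospitalization_rate,
         hypertension_rate = hypertension_rate),
    class = "cohortair_synth_config"
  )
}

# per-field, per-city missingness lookup
.miss_prob <- function(missingness, field, city) {
  v <- missingness[[field]]
  if (is.null(v)) return(0)
  v <- unlist(v)
  if (is.null(names(v)) || length(v) == 1L && is.null(names(v))) return(v[[1]])
  if (city %in% names(v)) return(unname(v[[city]]))
  if ("default" %in% names(v)) return(unname(v[["default"]]))
  unname(v[[1]])
}
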