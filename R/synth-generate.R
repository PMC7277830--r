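#' Generate a daily background-monitor series
#'
#' Produces one concentration value per calendar day over the configured year
#' range for a given city and pollutant, following the seasonal/declining
#' model of [monitor_spec()]. The sub-seed is derived deterministically from
#' the configuration seed and the city/pollutant, so the same series is
#' obtained standalone or inside [generate_cohort()].
#'
#' @param config A [synth_config()].
#' @param city City name (must be in `config$cities`).
#' @param pollutant Pollutant name (must be in `config$pollutants`).
#' @return Tibble with columns `city`, `pollutant`, `date`, `value`.
#' @export
generate_monitor_series <- function(config, city, pollutant) {
  stopifnot(inherits(config, "cohortair_synth_config"))
  cities <- vapply(config$cities, `[[`, "", "name")
  .assert_config(city %in% cities, "city", "is not in the configuration")
  .assert_config(pollutant %in% config$pollutants, "pollutant",
                 "is not in the configuration")
  spec <- config$monitor[[pollutant]]
  set.seed(.sub_seed(config$seed, match(city, cities) * 131L +
                       match(pollutant, config$pollutants)))
  # monitors run 2007-2013 regardless of the birth-year range (extended if
  # births fall outside); the decline is anchored at 2007
  y0 <- 2007L
  dates <- seq(as.Date(sprintf("%d-01-01", min(y0, config$year_range[1]))),
               as.Date(sprintf("%d-12-31",
                               max(2013L, config$year_range[2]))), by = "day")
  doy <- as.POSIXlt(dates)$yday + 1
  yr <- as.POSIXlt(dates)$year + 1900
  seasonal <- 1 + spec$amplitude * cos(2 * pi * (doy - spec$peak_doy) / 365.25)
  trend <- (1 - spec$decline)^(yr - y0)
  value <- spec$baseline * seasonal * trend +
    stats::rnorm(length(dates), 0, spec$noise_sd)
  tibble::tibble(city = city, pollutant = pollutant, date = dates,
                 value = pmax(value, 0))
}

.sub_seed <- function(seed, idx) {
  (abs(seed) * 48271 + idx * 9973) %% 2147483647L
}

# gestational-age pmf over completed weeks 24..42 with the configured
# preterm (<37 wk) mass; term part peaks at 39-40 wk (certificate means
# ~39.0, sd ~1.8)
.ga_pmf <- function(preterm_rate) {
  weeks <- 24:42
  pre <- 1.4^(0:12)
  pre <- pre / sum(pre) * preterm_rate
  term <- c(0.08, 0.21, 0.32, 0.25, 0.11, 0.03) * (1 - preterm_rate)
  list(weeks = weeks, prob = c(pre, term))
}

.apgar_pmf <- function() {
  p <- c(0.0002, 0.0002, 0.0003, 0.0005, 0.0010, 0.0013, 0.0017,
         0.0100, 0.0600, 0.4200, 0.5048)
  p / sum(p)
}

#' Generate a complete synthetic registry bundle
#'
#' Emits every table the pipeline consumes: delivery certificates, residence
#' episodes, census blocks with deprivation components, address-level
#' modelled annual concentrations, daily monitor series, hospital discharge
#' records and the reference growth table — together with a ground-truth
#' table recording which linkage-failure class (if any) each mother was
#' planted into. Planting is mutually exclusive, so the selection audit of
#' [apply_cascade()] recovers the planted counts exactly.
#'
#' Identical seed and configuration reproduce the bundle bit-for-bit.
#'
#' @param config A [synth_config()].
#' @return A list of class `cohortair_bundle` with elements `births`,
#'   `episodes`, `blocks`, `concentrations`, `monitors`, `hospital`,
#'   `growth_table`, `truth` and `config`.
#' @export
#' @examples
#' cfg <- synth_config(seed = 1, cities = list(city_spec("Alpha", 100)),
#'                     year_range = c(2007, 2007))
#' b <- generate_cohort(cfg)
#' nrow(b$births)
generate_cohort <- function(config) {
  if (!inherits(config, "cohortair_synth_config"))
    stop("invalid configuration: `config` must come from synth_config()",
         call. = FALSE)
  growth <- reference_growth_table()
  years <- seq(config$year_range[1], config$year_range[2])

  monitors <- dplyr::bind_rows(lapply(config$cities, function(cs) {
    dplyr::bind_rows(lapply(config$pollutants, function(p)
      generate_monitor_series(config, cs$name, p)))
  }))

  blocks <- dplyr::bind_rows(lapply(seq_along(config$cities), function(ci) {
    .gen_blocks(config, ci)
  }))

  per_city <- lapply(seq_along(config$cities), function(ci) {
    .gen_city_cohort(config, ci, blocks, growth, years)
  })

  bundle <- list(
    births = dplyr::bind_rows(lapply(per_city, `[[`, "births")),
    episodes = dplyr::bind_rows(lapply(per_city, `[[`, "episodes")),
    blocks = blocks,
    concentrations = dplyr::bind_rows(lapply(per_city, `[[`, "concentrations")),
    monitors = monitors,
    hospital = dplyr::bind_rows(lapply(per_city, `[[`, "hospital")),
    growth_table = growth,
    truth = dplyr::bind_rows(lapply(per_city, `[[`, "truth")),
    config = config
  )
  class(bundle) <- "cohortair_bundle"
  bundle
}

# census blocks for city ci: a latent level drives the five component
# percentages; the block's realized deprivation signal (standardized
# component sum, i.e. what the index will rank on) later drives address
# concentrations with the configured per-pollutant correlation, so at
# |rho| = 1 concentration is a deterministic monotone function of the score
.gen_blocks <- function(config, ci) {
  cs <- config$cities[[ci]]
  set.seed(.sub_seed(config$seed, ci * 7919L))
  nb <- cs$n_census_blocks
  latent <- stats::rnorm(nb)
  comp <- function(a, b, s) 100 * stats::plogis(a + b * latent +
                                                  stats::rnorm(nb, 0, s))
  out <- tibble::tibble(
    block_id = sprintf("%s_B%04d", cs$name, seq_len(nb)),
    city = cs$name,
    resident_population = sample(300:2500, nb, replace = TRUE),
    pct_low_education = comp(-1.2, 0.8, 0.3),
    pct_unemployment = comp(-2.2, 0.7, 0.3),
    pct_home_tenancy = comp(-0.9, 0.6, 0.3),
    pct_lone_parent = comp(-2.0, 0.5, 0.3),
    pct_overcrowding = comp(-2.5, 0.8, 0.3),
    census_year = 2011L
  )
  zsum <- rowSums(scale(as.matrix(out[, c(
    "pct_low_education", "pct_unemployment", "pct_home_tenancy",
    "pct_lone_parent", "pct_overcrowding")])))
  out$latent_deprivation <- as.numeric(scale(zsum))
  out
}

.gen_city_cohort <- function(config, ci, blocks, growth, years) {
  cs <- config$cities[[ci]]
  set.seed(.sub_seed(config$seed, ci * 104729L))
  cb <- blocks[blocks$city == cs$name, ]
  npy <- cs$n_births_per_year
  n <- npy * length(years)
  mother_id <- sprintf("%s_M%07d", cs$name, seq_len(n))

  year <- rep(years, each = npy)
  ydays <- ifelse(year %% 4 == 0 & (year %% 100 != 0 | year %% 400 == 0),
                  366L, 365L)
  delivery_date <- as.Date(sprintf("%d-01-01", year)) +
    floor(stats::runif(n) * ydays)

  ga <- .ga_pmf(config$preterm_rate)
  gestational_weeks <- sample(ga$weeks, n, replace = TRUE, prob = ga$prob)
  lmp_date <- delivery_date - 7L * gestational_weeks

  parity <- sample(c("first", "second", "higher"), n, replace = TRUE,
                   prob = c(0.54, 0.35, 0.11))
  infant_sex <- sample(c("boy", "girl"), n, replace = TRUE,
                       prob = c(0.515, 0.485))
  key <- paste(infant_sex, gestational_weeks, parity)
  gkey <- paste(growth$infant_sex, growth$gestational_week,
                growth$parity_class)
  gi <- match(key, gkey)
  birthweight <- round(stats::rnorm(n, growth$mean_g[gi], growth$sd_g[gi]))
  birthweight <- pmax(birthweight, 300)

  maternal_age <- pmin(pmax(round(stats::rnorm(n, 32.5, 5.2)), 15L), 49L)
  education <- sample(c("university", "high school", "junior high school",
                        "primary"), n, replace = TRUE,
                      prob = c(0.27, 0.47, 0.20, 0.06))
  occupation <- sample(c("employed", "unemployed", "looking_first_job",
                         "student", "housewife", "other"), n, replace = TRUE,
                       prob = c(0.708, 0.083, 0.009, 0.014, 0.182, 0.004))
  marital_status <- sample(c("married", "not married", "separated",
                             "divorced", "widowed"), n, replace = TRUE,
                           prob = c(0.664, 0.307, 0.017, 0.010, 0.002))
  citizenship <- sample(c("Italian", "foreigner"), n, replace = TRUE,
                        prob = c(0.80, 0.20))
  delivery_type <- sample(c("natural", "caesarean", "assisted", "other"),
                          n, replace = TRUE,
                          prob = c(0.583, 0.381, 0.035, 0.001))
  previous_pregnancies <- ifelse(parity == "first", 0L,
                                 ifelse(parity == "second", 1L,
                                        2L + stats::rpois(n, 0.5))) +
    stats::rpois(n, 0.15)
  previous_abortions <- stats::rpois(n, 0.15)
  apgar <- sample(0:10, n, replace = TRUE, prob = .apgar_pmf())
  length_cm <- round(stats::rnorm(n, 49.9, 2.5), 1)
  cranial_cm <- round(stats::rnorm(n, 34.2, 2.0), 1)

  # mutually exclusive planted failure classes
  planted <- sample(
    c("none", "no_address", "out_of_city_gap", "missing_exposure",
      "malformation", "missing_outcome"), n, replace = TRUE,
    prob = c(1 - config$geocoding_missing_rate - config$out_of_city_rate -
               config$exposure_missing_rate - config$malformation_rate -
               config$outcome_missing_rate,
             config$geocoding_missing_rate, config$out_of_city_rate,
             config$exposure_missing_rate, config$malformation_rate,
             config$outcome_missing_rate))
  malformation <- planted == "malformation"
  # missing-outcome mothers lose one of the Table-footnote fields that do
  # not feed the pregnancy interval
  om <- which(planted == "missing_outcome")
  om_field <- rep_len(c("birthweight", "infant_sex", "parity"),
                      length(om))
  birthweight[om[om_field == "birthweight"]] <- NA_integer_
  infant_sex[om[om_field == "infant_sex"]] <- NA_character_
  parity[om[om_field == "parity"]] <- NA_character_

  for (f in c("education", "occupation", "marital_status", "citizenship")) {
    pmiss <- .miss_prob(config$missingness, f, cs$name)
    if (pmiss > 0) {
      v <- get(f)
      v[stats::runif(n) < pmiss] <- NA_character_
      assign(f, v)
    }
  }

  births <- tibble::tibble(
    mother_id, city = cs$name, delivery_date, lmp_date, maternal_age,
    education, occupation, marital_status, citizenship, parity,
    previous_pregnancies, previous_abortions, gestational_weeks,
    delivery_type, infant_sex, birthweight, length = length_cm,
    cranial_circumference = cranial_cm, apgar,
    singleton = TRUE, livebirth = TRUE, malformation
  )

  res <- .gen_episodes(config, cs, cb, births, planted)

  hosp <- .gen_hospital(config, births)

  truth <- tibble::tibble(
    mother_id,
    planted,
    expected_exclusion = dplyr::case_match(
      planted,
      c("no_address", "out_of_city_gap") ~ "missing_geocoding",
      "missing_exposure" ~ "missing_exposure",
      "malformation" ~ "malformation",
      "missing_outcome" ~ "missing_outcome",
      .default = "none"
    )
  )

  list(births = births, episodes = res$episodes,
       concentrations = res$concentrations, hospital = hosp, truth = truth)
}

# residence episodes + address concentrations for one city.
# Addresses are abstract ids tied to a census block; the block is sampled
# proportionally to resident population. Concentrations at an address are
# baseline * (1 + 0.25 * A) with A = rho * block latent + sqrt(1-rho^2) * eps,
# so the deprivation-pollution correlation has the configured sign/strength
# (deterministic monotone at |rho| = 1).
.gen_episodes <- function(config, cs, cb, births, planted) {
  n <- nrow(births)
  has_addr <- planted != "no_address"
  mover <- stats::runif(n) < config$mobility_rate & has_addr
  gest_days <- as.integer(births$delivery_date - births$lmp_date)

  pre_days <- sample(30:400, n, replace = TRUE)
  post_days <- sample(30:200, n, replace = TRUE)
  move_day <- pmin(pmax(floor(stats::runif(n) * (gest_days - 40)) + 20, 20),
                   gest_days - 20)

  bprob <- cb$resident_population / sum(cb$resident_population)
  b1 <- sample(nrow(cb), n, replace = TRUE, prob = bprob)
  b2 <- sample(nrow(cb), n, replace = TRUE, prob = bprob)

  gap_len <- sample(5:30, n, replace = TRUE)
  gap_start <- pmin(pmax(floor(stats::runif(n) *
                                 (gest_days - gap_len - 20)) + 10, 10),
                    gest_days - gap_len - 5)
  oog <- planted == "out_of_city_gap"

  idx <- which(has_addr)
  ep1 <- tibble::tibble(
    mother_id = births$mother_id[idx],
    address_id = paste0(births$mother_id[idx], "_A1"),
    block_idx = b1[idx],
    city = cs$name,
    start_date = births$lmp_date[idx] - pre_days[idx],
    end_date = dplyr::case_when(
      oog[idx] ~ births$lmp_date[idx] + gap_start[idx],
      mover[idx] ~ births$lmp_date[idx] + move_day[idx],
      TRUE ~ births$delivery_date[idx] + post_days[idx]
    )
  )
  idx2 <- which(has_addr & (mover | oog))
  ep2 <- tibble::tibble(
    mother_id = births$mother_id[idx2],
    address_id = paste0(births$mother_id[idx2], "_A2"),
    block_idx = ifelse(oog[idx2], b1[idx2], b2[idx2]),
    city = cs$name,
    start_date = dplyr::if_else(
      oog[idx2],
      births$lmp_date[idx2] + gap_start[idx2] + gap_len[idx2],
      births$lmp_date[idx2] + move_day[idx2]
    ),
    end_date = births$delivery_date[idx2] + post_days[idx2]
  )
  # a mover who also has an out-of-city gap keeps the same address across
  # the gap; ids must still be unique per (mother, interval)
  episodes <- dplyr::arrange(dplyr::bind_rows(ep1, ep2),
                             .data$mother_id, .data$start_date)
  episodes$census_block_id <- cb$block_id[episodes$block_idx]

  # address-level modelled annual concentrations
  addr <- unique(episodes[, c("address_id", "block_idx")])
  rho <- cs$deprivation_pollution_correlation[config$pollutants]
  conc <- dplyr::bind_rows(lapply(config$pollutants, function(p) {
    r <- rho[[p]]
    eps <- stats::rnorm(nrow(addr))
    a <- r * cb$latent_deprivation[addr$block_idx] + sqrt(1 - r^2) * eps
    base <- config$monitor[[p]]$baseline
    tibble::tibble(address_id = addr$address_id, pollutant = p,
                   annual_conc = pmax(base * (1 + 0.25 * a), 1))
  }))
  # planted missing exposure: first address of those mothers loses its row
  # for the first configured pollutant
  drop_m <- births$mother_id[planted == "missing_exposure"]
  drop_a <- paste0(drop_m, "_A1")
  conc <- conc[!(conc$address_id %in% drop_a &
                   conc$pollutant == config$pollutants[1]), ]

  episodes$block_idx <- NULL
  list(episodes = episodes[, c("mother_id", "address_id", "census_block_id",
                               "city", "start_date", "end_date")],
       concentrations = conc)
}

.gen_hospital <- function(config, births) {
  n <- nrow(births)
  adm <- which(stats::runif(n) < config$hospitalization_rate)
  if (length(adm) == 0L) {
    return(tibble::tibble(mother_id = character(), admission_date = as.Date(character()),
                          discharge_date = as.Date(character()),
                          diagnosis_codes = character()))
  }
  gest <- as.integer(births$delivery_date - births$lmp_date)[adm]
  day <- floor(stats::runif(length(adm)) * gest)
  admission <- births$lmp_date[adm] + day
  hyp <- stats::runif(length(adm)) < config$hypertension_rate
  codes <- ifelse(
    hyp,
    sample(c("6420", "6423", "6424", "6425", "6426", "6427", "6429"),
           length(adm), replace = TRUE),
    sample(c("650", "6489", "V270", "64893", "66970"),
           length(adm), replace = TRUE))
  tibble::tibble(
    mother_id = births$mother_id[adm],
    admission_date = admission,
    discharge_date = admission + sample(0:10, length(adm), replace = TRUE),
    diagnosis_codes = codes
  )
}
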