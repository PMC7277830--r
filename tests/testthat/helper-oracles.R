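# Brute-force oracles, kept deliberately naive and independent of the
# package's vectorised implementations.

# day-by-day covered-day count of [ws, we) by a set of [start, end) episodes
oracle_covered_days <- function(episodes, ws, we) {
  days <- seq(ws, we - 1, by = "day")
  covered <- vapply(days, function(d) {
    any(episodes$start_date <= d & d < episodes$end_date)
  }, logical(1))
  sum(covered)
}

# day-by-day residence weights over a window
oracle_weights <- function(episodes, window) {
  days <- seq(window[1], window[2] - 1, by = "day")
  addr <- character(0)
  for (d in seq_along(days)) {
    hit <- which(episodes$start_date <= days[d] & days[d] < episodes$end_date)
    if (length(hit)) addr <- c(addr, episodes$address_id[max(hit)])
  }
  tab <- table(addr)
  tibble::tibble(address_id = names(tab),
                 weight = as.numeric(tab) / sum(tab))
}

# day-by-day extrapolated mean: conc(address on day) * ratio(day)
oracle_back_extrapolate <- function(episodes, concentrations, ratio_tbl,
                                    window, pollutant) {
  days <- seq(window[1], window[2] - 1, by = "day")
  vals <- vapply(days, function(d) {
    hit <- which(episodes$start_date <= d & d < episodes$end_date)
    a <- episodes$address_id[max(hit)]
    cc <- concentrations$annual_conc[
      concentrations$address_id == a & concentrations$pollutant == pollutant]
    r <- ratio_tbl$ratio[ratio_tbl$date == d]
    cc * r
  }, numeric(1))
  mean(vals)
}

# day-by-day standard exposure: mean over days of conc(address on day)
oracle_standard_exposure <- function(episodes, concentrations, window,
                                     pollutant) {
  days <- seq(window[1], window[2] - 1, by = "day")
  vals <- vapply(days, function(d) {
    hit <- which(episodes$start_date <= d & d < episodes$end_date)
    a <- episodes$address_id[max(hit)]
    concentrations$annual_conc[
      concentrations$address_id == a & concentrations$pollutant == pollutant]
  }, numeric(1))
  mean(vals)
}

# cumulative-population walk for quintile assignment (one city)
oracle_quintiles <- function(block_id, score, population) {
  o <- order(score, block_id)
  tot <- sum(population)
  cuts <- tot * (1:4) / 5
  q <- integer(length(score))
  cum <- 0
  cur <- 1L
  for (i in o) {
    q[i] <- cur
    cum <- cum + population[i]
    while (cur < 5L && cum >= cuts[cur]) cur <- cur + 1L
  }
  q
}

# non-overlapping random episode fixture fully covering `window`, with
# k address changes at random cut days; returns episodes + concentrations
random_episode_fixture <- function(window, k_addresses = sample(1:4, 1),
                                   pollutant = "PM10") {
  len <- as.integer(window[2] - window[1])
  cuts <- sort(sample(seq_len(len - 1), k_addresses - 1))
  bounds <- c(0L, cuts, len)
  eps <- tibble::tibble(
    mother_id = "m1",
    address_id = sprintf("a%d", seq_len(k_addresses)),
    census_block_id = "b1", city = "X",
    start_date = window[1] + bounds[-length(bounds)],
    end_date = window[1] + bounds[-1])
  conc <- tibble::tibble(address_id = eps$address_id, pollutant = pollutant,
                         annual_conc = stats::runif(k_addresses, 10, 60))
  list(episodes = eps, concentrations = conc)
}

# minimal one-row birth record for selection tests
make_birth <- function(mother_id = "m1", city = "X",
                       delivery_date = as.Date("2010-10-15"),
                       gestational_weeks = 39L,
                       maternal_age = 30, singleton = TRUE, livebirth = TRUE,
                       malformation = FALSE, birthweight = 3300L,
                       infant_sex = "girl", parity = "first", ...) {
  tibble::tibble(
    mother_id = mother_id, city = city, delivery_date = delivery_date,
    lmp_date = delivery_date - 7L * gestational_weeks,
    maternal_age = maternal_age, education = "high school",
    occupation = "employed", marital_status = "married",
    citizenship = "Italian", parity = parity, previous_pregnancies = 0L,
    previous_abortions = 0L, gestational_weeks = gestational_weeks,
    delivery_type = "natural", infant_sex = infant_sex,
    birthweight = birthweight, length = 50, cranial_circumference = 34,
    apgar = 9L, singleton = singleton, livebirth = livebirth,
    malformation = malformation, ...)
}

# constant-value monitor tibble for one city/pollutant
constant_monitor <- function(value = 40, city = "X", pollutant = "PM10",
                             from = as.Date("2007-01-01"),
                             to = as.Date("2013-12-31")) {
  dates <- seq(from, to, by = "day")
  tibble::tibble(city = city, pollutant = pollutant, date = dates,
                 value = value)
}

# small two-city synthetic configuration used across tests
small_config <- function(seed = 11, n = 250, years = c(2008, 2009), ...) {
  synth_config(
    seed = seed,
    cities = list(
      city_spec("Alpha", n, 40,
                c(PM10 = 1, "PM2.5" = 0.4, NO2 = -1)),
      city_spec("Beta", n, 30,
                c(PM10 = -0.6, "PM2.5" = 0, NO2 = 0.6))),
    year_range = years, ...)
}
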