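test_that("pregnancy windows follow the day-count conventions", {
  w <- build_windows(as.Date("2010-01-15"), as.Date("2010-10-15"))
  expect_equal(w$gestation_days, 273L)            # 39 weeks
  expect_equal(w$trimester1, as.Date(c("2010-01-15", "2010-04-15")))
  expect_equal(w$trimester2, as.Date(c("2010-04-15", "2010-07-14")))
  expect_equal(w$trimester3[2], as.Date("2010-10-15"))
  expect_equal(w$season_of_conception, "winter")
  expect_equal(as.integer(w$last_week[2] - w$last_week[1]), 7L)
  expect_equal(as.integer(w$first_five_months[2] - w$first_five_months[1]),
               150L)
  expect_true(w$valid)
})

test_that("trimesters partition the pregnancy for gestations over 180 days", {
  for (weeks in c(27, 33, 39, 42)) {
    lmp <- as.Date("2009-03-01")
    w <- build_windows(lmp, lmp + weeks * 7L)
    d1 <- as.integer(w$trimester1[2] - w$trimester1[1])
    d2 <- as.integer(w$trimester2[2] - w$trimester2[1])
    d3 <- as.integer(w$trimester3[2] - w$trimester3[1])
    expect_equal(d1 + d2 + d3, w$gestation_days)
  }
})

test_that("short gestations flag an empty third trimester; bad dates error", {
  lmp <- as.Date("2011-06-01")
  w <- build_windows(lmp, lmp + 25L * 7L)          # 175 days
  expect_true("trimester3_empty" %in% w$flags)
  expect_equal(as.integer(w$trimester3[2] - w$trimester3[1]), 0L)
  expect_false(build_windows(lmp, lmp + 100L)$valid)
  expect_error(build_windows(lmp, lmp), "precede")
})

test_that("season of conception follows the LMP month", {
  lmps <- as.Date(c("2010-12-10", "2010-02-20", "2010-03-01", "2010-05-31",
                    "2010-06-01", "2010-08-31", "2010-09-01", "2010-11-30"))
  seasons <- vapply(lmps, function(d)
    build_windows(d, d + 273L)$season_of_conception, "")
  expect_equal(seasons, c("winter", "winter", "spring", "spring", "summer",
                          "summer", "autumn", "autumn"))
})

test_that("residence weights: single address and exact thirds", {
  lmp <- as.Date("2010-01-01")
  w1 <- residence_weights(tibble::tibble(
    address_id = "a", start_date = lmp - 50, end_date = lmp + 400),
    c(lmp, lmp + 273))
  expect_equal(w1$weight, 1.0)

  eps <- tibble::tibble(address_id = c("a1", "a2"),
                        start_date = c(lmp - 10, lmp + 90),
                        end_date = c(lmp + 90, lmp + 300))
  w2 <- residence_weights(eps, c(lmp, lmp + 270))
  expect_equal(w2$weight[w2$address_id == "a1"], 1 / 3)
  expect_equal(w2$weight[w2$address_id == "a2"], 2 / 3)
})

test_that("uncovered windows error unless within tolerance", {
  lmp <- as.Date("2010-01-01")
  eps <- tibble::tibble(address_id = "a", start_date = lmp + 5,
                        end_date = lmp + 270)
  expect_error(residence_weights(eps, c(lmp, lmp + 270)), "uncovered")
  w <- residence_weights(eps, c(lmp, lmp + 270), tolerance_days = 7)
  expect_equal(sum(w$weight), 1)
})

test_that("standard exposure is the weighted concentration mean", {
  conc <- tibble::tibble(address_id = c("a1", "a2"), pollutant = "PM10",
                         annual_conc = c(30, 45))
  w <- tibble::tibble(address_id = "a1", days = 10L, weight = 1)
  expect_equal(standard_exposure(
    tibble::tibble(address_id = "a1", days = 1L, weight = 1),
    tibble::tibble(address_id = "a1", pollutant = "NO2",
                   annual_conc = 46.7), "NO2"), 46.7)
  w2 <- tibble::tibble(address_id = c("a1", "a2"), days = c(90L, 180L),
                       weight = c(1 / 3, 2 / 3))
  expect_equal(standard_exposure(w2, conc, "PM10"), 40.0)
  expect_error(standard_exposure(w2, conc[1, ], "PM10"), "a2")
})

test_that("campaign mean: constant, alternating, generator closed form, gaps", {
  expect_equal(compute_mlur(constant_monitor(40)), 40)

  alt <- constant_monitor(0, from = as.Date("2010-01-01"),
                          to = as.Date("2010-12-31"))
  alt$value <- rep(c(30, 50), length.out = nrow(alt))
  # 365 days: mean over an even alternation of the first 364 plus one 30
  expect_equal(compute_mlur(alt), mean(alt$value))
  expect_equal(compute_mlur(alt[1:364, ], lur_period = as.Date(
    c("2010-01-01", "2010-12-30"))), 40)

  # noise-free generator series: closed-form campaign mean
  cfg <- synth_config(seed = 1, cities = list(city_spec("Solo", 10, 5)),
                      monitor = list(
                        PM10 = monitor_spec(40, amplitude = 0.3,
                                            decline = 0.05, noise_sd = 0,
                                            peak_doy = 1),
                        "PM2.5" = monitor_spec(22), NO2 = monitor_spec(45)))
  s <- generate_monitor_series(cfg, "Solo", "PM10")
  s10 <- s[format(s$date, "%Y") == "2010", ]
  doy <- as.POSIXlt(s10$date)$yday + 1
  closed <- mean(40 * (1 + 0.3 * cos(2 * pi * (doy - 1) / 365.25)) * 0.95^3)
  expect_equal(compute_mlur(s[, c("date", "value")]), closed,
               tolerance = 1e-9)

  # missing-day policy: <=10% tolerated with a message, more is an error
  holey <- constant_monitor(40, from = as.Date("2010-01-01"),
                            to = as.Date("2010-12-31"))
  expect_message(compute_mlur(holey[-(1:30), ]), "missing")
  expect_error(compute_mlur(holey[-(1:60), ]), "missing")
})

test_that("daily ratio: identity, zero, and linear interpolation of short gaps", {
  mon <- constant_monitor(40, from = as.Date("2010-01-01"),
                          to = as.Date("2010-12-31"))
  expect_equal(daily_ratio(mon, as.Date("2010-06-15")), 1.0)
  mon2 <- mon
  mon2$value[mon2$date == as.Date("2010-06-15")] <- 0
  expect_equal(daily_ratio(mon2, as.Date("2010-06-15")), 0.0,
               tolerance = 1e-12)

  # one missing day flanked by 30 and 50 interpolates to 40
  mon3 <- mon
  mon3$value[mon3$date == as.Date("2010-06-14")] <- 30
  mon3$value[mon3$date == as.Date("2010-06-16")] <- 50
  mon3 <- mon3[mon3$date != as.Date("2010-06-15"), ]
  m <- compute_mlur(mon3)
  expect_equal(daily_ratio(mon3, as.Date("2010-06-15"), m_lur = m), 40 / m,
               tolerance = 1e-12)

  # gaps beyond the limit error naming the date range
  mon4 <- mon[!(mon$date >= as.Date("2010-06-01") &
                  mon$date <= as.Date("2010-06-10")), ]
  expect_error(daily_ratio(mon4, as.Date("2010-06-05"), m_lur = 40,
                           max_gap_days = 7), "2010-06-05")
  expect_equal(daily_ratio(mon4, as.Date("2010-06-05"), m_lur = 40,
                           max_gap_days = 10), 1.0)
})

test_that("back-extrapolation reduces to the standard model when ratio is 1", {
  set.seed(42)
  lmp <- as.Date("2010-02-01")
  window <- c(lmp, lmp + 273L)
  fx <- random_episode_fixture(window, 3)
  mon <- constant_monitor(40)
  rs <- daily_ratio_series(mon)
  w <- residence_weights(fx$episodes, window)
  std <- standard_exposure(w, fx$concentrations, "PM10")
  expect_equal(back_extrapolate(fx$episodes, fx$concentrations, rs, window,
                                "PM10"), std, tolerance = 1e-12)
})

test_that("single-address back-extrapolation factorizes as conc x mean ratio", {
  lmp <- as.Date("2011-03-01")
  window <- c(lmp, lmp + 280L)
  eps <- tibble::tibble(mother_id = "m", address_id = "a",
                        start_date = lmp - 30, end_date = lmp + 400)
  conc <- tibble::tibble(address_id = "a", pollutant = "NO2",
                         annual_conc = 52.3)
  cfg <- synth_config(seed = 8, cities = list(city_spec("Solo", 10, 5)))
  mon <- generate_monitor_series(cfg, "Solo", "NO2")
  rs <- daily_ratio_series(mon[, c("date", "value")])
  days <- seq(window[1], window[2] - 1, by = "day")
  expect_equal(
    back_extrapolate(eps, conc, rs, window, "NO2"),
    52.3 * mean(rs$ratio[match(days, rs$date)]), tolerance = 1e-12)
})

test_that("back-extrapolation is linear in the address concentrations", {
  set.seed(9)
  lmp <- as.Date("2010-05-01")
  window <- c(lmp, lmp + 260L)
  fx <- random_episode_fixture(window, 4)
  cfg <- synth_config(seed = 8, cities = list(city_spec("Solo", 10, 5)))
  mon <- generate_monitor_series(cfg, "Solo", "PM10")
  rs <- daily_ratio_series(mon[, c("date", "value")])
  base <- back_extrapolate(fx$episodes, fx$concentrations, rs, window, "PM10")
  scaled <- fx$concentrations
  scaled$annual_conc <- scaled$annual_conc * 2.5
  expect_equal(back_extrapolate(fx$episodes, scaled, rs, window, "PM10"),
               2.5 * base, tolerance = 1e-12)
})

test_that("exposure summary gives per-city mean and n-1 sd", {
  prof <- tibble::tibble(city = "A", pollutant = "PM10",
                         standard_exposure = c(30, 50))
  s <- exposure_summary(prof)
  expect_equal(s$mean, 40)
  expect_equal(s$sd, sqrt(200))
  prof2 <- tibble::tibble(city = "A", pollutant = "PM10",
                          standard_exposure = rep(33.3, 5))
  expect_equal(exposure_summary(prof2)$sd, 0)
})

test_that("batch profiles agree with the single-mother operations", {
  cfg <- small_config(seed = 31, n = 40, mobility_rate = 0.5,
                      geocoding_missing_rate = 0, out_of_city_rate = 0,
                      exposure_missing_rate = 0)
  b <- generate_cohort(cfg)
  sel <- select_initial(b$births)
  casc <- apply_cascade(sel$selected, b$episodes, b$concentrations,
                        cfg$pollutants)
  prof <- exposure_profiles(casc$analysed, b$episodes, b$concentrations,
                            b$monitors, cfg$pollutants)
  pick <- prof[prof$back_available & prof$pollutant == "PM10", ][1:5, ]
  for (i in seq_len(nrow(pick))) {
    m <- pick$mother_id[i]
    rec <- casc$analysed[casc$analysed$mother_id == m, ]
    eps <- b$episodes[b$episodes$mother_id == m, ]
    w <- build_windows(rec$lmp_date, rec$delivery_date)
    wt <- residence_weights(eps, w$whole)
    expect_equal(pick$standard_exposure[i],
                 standard_exposure(wt, b$concentrations, "PM10"),
                 tolerance = 1e-12)
    mon <- b$monitors[b$monitors$city == rec$city &
                        b$monitors$pollutant == "PM10", ]
    rs <- daily_ratio_series(mon[, c("date", "value")])
    expect_equal(pick$back_whole[i],
                 back_extrapolate(eps, b$concentrations, rs, w$whole, "PM10"),
                 tolerance = 1e-12)
    expect_equal(pick$back_trimester2[i],
                 back_extrapolate(eps, b$concentrations, rs, w$trimester2,
                                  "PM10"), tolerance = 1e-12)
    expect_equal(pick$back_last_week[i],
                 back_extrapolate(eps, b$concentrations, rs, w$last_week,
                                  "PM10"), tolerance = 1e-12)
  }
  # births outside the eligible years carry no back-extrapolation
  prof07 <- exposure_profiles(casc$analysed, b$episodes, b$concentrations,
                              b$monitors, cfg$pollutants,
                              backextrap_years = c(2100L, 2100L))
  expect_true(all(!prof07$back_available))
  expect_true(all(is.na(prof07$back_whole)))
  expect_false(any(is.na(prof07$standard_exposure)))
})
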