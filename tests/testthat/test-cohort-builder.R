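test_that("demographic selection keeps 15-49, singleton, livebirth (bounds inclusive)", {
  recs <- dplyr::bind_rows(
    make_birth("m14", maternal_age = 14),
    make_birth("m15", maternal_age = 15),
    make_birth("m49", maternal_age = 49),
    make_birth("m50", maternal_age = 50),
    make_birth("twin", singleton = FALSE),
    make_birth("still", livebirth = FALSE))
  sel <- select_initial(recs)
  expect_setequal(sel$selected$mother_id, c("m15", "m49"))
  expect_equal(nrow(sel$rejected), 0)
})

test_that("records with missing singleton/livebirth flags go to the reject log", {
  recs <- dplyr::bind_rows(make_birth("ok"), make_birth("noflag"))
  recs$singleton[recs$mother_id == "noflag"] <- NA
  sel <- select_initial(recs)
  expect_equal(sel$selected$mother_id, "ok")
  expect_equal(sel$rejected$mother_id, "noflag")
  expect_match(sel$rejected$reject_reason, "flag")
})

test_that("year-range selection uses the delivery year", {
  recs <- dplyr::bind_rows(
    make_birth("a", delivery_date = as.Date("2006-12-31")),
    make_birth("b", delivery_date = as.Date("2007-01-01")),
    make_birth("c", delivery_date = as.Date("2013-12-31")),
    make_birth("d", delivery_date = as.Date("2014-01-01")))
  sel <- select_initial(recs, year_range = c(2007, 2013))
  expect_setequal(sel$selected$mother_id, c("b", "c"))
})

test_that("coverage filter handles supersets, exact covers, gaps and tolerance", {
  rec <- make_birth("m1")
  lmp <- rec$lmp_date; del <- rec$delivery_date
  sup <- tibble::tibble(mother_id = "m1", address_id = "a1",
                        census_block_id = "b", city = "X",
                        start_date = lmp - 100, end_date = del + 10)
  expect_true(coverage_filter(rec, sup))

  split_day <- lmp + 120
  abut <- tibble::tibble(mother_id = "m1",
                         address_id = c("a1", "a2"),
                         census_block_id = "b", city = "X",
                         start_date = c(lmp, split_day),
                         end_date = c(split_day, del))
  expect_true(coverage_filter(rec, abut))

  gap <- abut
  gap$end_date[1] <- split_day - 5   # 5-day hole mid-pregnancy
  expect_false(coverage_filter(rec, gap))
  expect_true(coverage_filter(rec, gap, tolerance_days = 7))
  expect_equal(oracle_covered_days(gap, lmp, del),
               as.integer(del - lmp) - 5L)

  expect_false(coverage_filter(rec, sup[0, ]))          # no episodes at all
  other_city <- sup; other_city$city <- "Y"
  expect_false(coverage_filter(rec, other_city))        # out-of-city only
})

test_that("audit arithmetic reproduces analysed counts and telescopes", {
  counts <- tibble::tibble(
    city = c("A", "B"), n_initial = c(1000L, 500L),
    n_missing_geocoding = c(30L, 5L), n_missing_exposure = c(10L, 2L),
    n_malformation = c(15L, 3L), n_missing_outcome = c(1L, 0L))
  a <- audit_from_counts(counts)
  expect_equal(a$n_analysed, c(944L, 490L, 1434L))
  expect_equal(a$n_initial - a$n_missing_geocoding - a$n_missing_exposure -
                 a$n_malformation - a$n_missing_outcome, a$n_analysed)
  expect_equal(a$city[3], "Total")
  expect_equal(a$pct_of_initial, round_half_up(100 * a$n_analysed /
                                                 a$n_initial, 1))
})

test_that("percentage rounding is half-up to one decimal", {
  expect_equal(round_half_up(100 * 45679 / 46376, 1), 98.5)
  expect_equal(round_half_up(0.25, 1), 0.3)
  expect_equal(round_half_up(c(98.44, 98.45, -1.25), 1), c(98.4, 98.5, -1.3))
})

test_that("empty input yields an all-zero audit", {
  recs <- make_birth("m1")[0, ]
  out <- apply_cascade(recs, recs[0, c("mother_id", "city")] |>
                         dplyr::mutate(address_id = character(),
                                       census_block_id = character(),
                                       start_date = as.Date(character()),
                                       end_date = as.Date(character())),
                       tibble::tibble(address_id = character(),
                                      pollutant = character(),
                                      annual_conc = numeric()))
  expect_equal(nrow(out$analysed), 0)
  expect_equal(sum(out$audit$n_initial), 0)
})

test_that("duplicate mother x delivery date is a registry-integrity error", {
  recs <- dplyr::bind_rows(make_birth("m1"), make_birth("m1"))
  expect_error(apply_cascade(recs, recs[0, ], tibble::tibble(
    address_id = character(), pollutant = character(),
    annual_conc = numeric())), "duplicate")
})

test_that("cascade counts each record once, at its first failing step", {
  # one mother failing both coverage and malformation lands in geocoding
  rec <- make_birth("m1", malformation = TRUE)
  out <- apply_cascade(rec, rec[0, c("mother_id", "city")] |>
                         dplyr::mutate(address_id = character(),
                                       census_block_id = character(),
                                       start_date = as.Date(character()),
                                       end_date = as.Date(character())),
                       tibble::tibble(address_id = character(),
                                      pollutant = character(),
                                      annual_conc = numeric()))
  expect_equal(out$audit$n_missing_geocoding[1], 1L)
  expect_equal(out$audit$n_malformation[1], 0L)
})

test_that("cascade audit equals the generator's planted failure classes", {
  cfg <- small_config(seed = 21, n = 900, mobility_rate = 0.2,
                      out_of_city_rate = 0.02,
                      geocoding_missing_rate = 0.03,
                      exposure_missing_rate = 0.025,
                      malformation_rate = 0.02,
                      outcome_missing_rate = 0.005)
  b <- generate_cohort(cfg)
  sel <- select_initial(b$births)
  out <- apply_cascade(sel$selected, b$episodes, b$concentrations,
                       cfg$pollutants)
  planted <- table(b$truth$expected_exclusion)
  tot <- out$audit[out$audit$city == "Total", ]
  expect_equal(tot$n_missing_geocoding,
               unname(planted["missing_geocoding"]))
  expect_equal(tot$n_missing_exposure, unname(planted["missing_exposure"]))
  expect_equal(tot$n_malformation, unname(planted["malformation"]))
  expect_equal(tot$n_missing_outcome, unname(planted["missing_outcome"]))
  expect_equal(tot$n_analysed, unname(planted["none"]))
  # telescoping per city and overall
  expect_equal(out$audit$n_initial,
               out$audit$n_missing_geocoding + out$audit$n_missing_exposure +
                 out$audit$n_malformation + out$audit$n_missing_outcome +
                 out$audit$n_analysed)
  # per-year analysed counts sum to the analysed total
  expect_equal(sum(out$audit_years$n_analysed), tot$n_analysed)
  # excluded + analysed partition the input
  expect_equal(nrow(out$analysed) + nrow(out$excluded), nrow(sel$selected))
})

test_that("audit renders as an aligned text table", {
  counts <- tibble::tibble(
    city = "A", n_initial = 100L, n_missing_geocoding = 2L,
    n_missing_exposure = 1L, n_malformation = 1L, n_missing_outcome = 0L)
  lines <- format_audit(audit_from_counts(counts))
  expect_true(any(grepl("N births analysed", lines)))
  expect_true(any(grepl("96", lines)))
})
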