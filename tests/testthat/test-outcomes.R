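test_that("preterm is strictly below 37 completed weeks", {
  expect_true(classify_preterm(36))
  expect_false(classify_preterm(37))
  expect_false(classify_preterm(42))
  expect_true(classify_preterm(24))
})

test_that("term low birthweight is <2500 g among term births only", {
  expect_true(classify_term_lbw(39, 2400))
  expect_false(classify_term_lbw(39, 2500))
  expect_true(is.na(classify_term_lbw(35, 2400)))
  expect_equal(classify_term_lbw(c(39, 39, 35), c(2400, 2500, 2400)),
               c(TRUE, FALSE, NA))
})

test_that("weight-for-GA boundaries are strict on both percentiles", {
  tab <- reference_growth_table()
  row <- tab[tab$infant_sex == "girl" & tab$gestational_week == 39 &
               tab$parity_class == "first", ]
  expect_equal(classify_weight_for_ga("girl", 39, "first", row$p10),
               "appropriate")
  expect_equal(classify_weight_for_ga("girl", 39, "first", row$p10 - 1),
               "small")
  expect_equal(classify_weight_for_ga("girl", 39, "first", row$p90),
               "appropriate")
  expect_equal(classify_weight_for_ga("girl", 39, "first", row$p90 + 1),
               "large")
  expect_error(classify_weight_for_ga("girl", 23, "first", 3000),
               "stratum")
})

test_that("a cohort drawn from the reference distribution is ~10% small", {
  cfg <- synth_config(seed = 13, cities = list(city_spec("Solo", 12000, 10)),
                      year_range = c(2010, 2010), outcome_missing_rate = 0)
  b <- generate_cohort(cfg)
  cls <- classify_weight_for_ga(b$births$infant_sex,
                                b$births$gestational_weeks,
                                b$births$parity, b$births$birthweight,
                                b$growth_table)
  p_small <- mean(cls == "small")
  tol <- 3 * sqrt(0.1 * 0.9 / nrow(b$births))
  expect_lt(abs(p_small - 0.10), tol)
})

test_that("Apgar bands follow the printed classes with 0 unclassified", {
  expect_equal(classify_apgar(c(7, 10, 4, 6, 3, 1, 0)),
               c("normal", "normal", "needs_assistance", "needs_assistance",
                 "needs_resuscitation", "needs_resuscitation",
                 "unclassified"))
})

test_that("hypertensive flags use undotted ICD-9 prefix matching in-window", {
  lmp <- as.Date("2010-01-15")
  del <- lmp + 273L
  births <- dplyr::bind_rows(
    make_birth("m1", delivery_date = del),
    make_birth("m2", delivery_date = del),
    make_birth("m3", delivery_date = del),
    make_birth("m4", delivery_date = del))
  hosp <- tibble::tibble(
    mother_id = c("m1", "m2", "m3", "m4"),
    admission_date = c(lmp + 100, del + 5, lmp + 50, lmp + 10),
    discharge_date = c(lmp + 105, del + 8, lmp + 52, lmp + 12),
    diagnosis_codes = c("6425", "6424", "642", "650;V270"))
  f <- detect_hypertensive(births, hosp)
  m1 <- f[f$mother_id == "m1", ]
  expect_true(m1$hypertension && m1$severe_preeclampsia &&
                m1$any_preeclampsia_eclampsia)
  expect_false(m1$mild_preeclampsia || m1$eclampsia)
  # admission after delivery never counts
  expect_false(any(unlist(f[f$mother_id == "m2", -1])))
  # bare 3-digit 642 sets the family flag only
  m3 <- f[f$mother_id == "m3", ]
  expect_true(m3$hypertension)
  expect_false(m3$mild_preeclampsia || m3$severe_preeclampsia ||
                 m3$eclampsia || m3$any_preeclampsia_eclampsia)
  expect_false(any(unlist(f[f$mother_id == "m4", -1])))
})

test_that("prefix matching agrees with an enumeration oracle over 642 codes", {
  codes <- c("642", sprintf("642%d", 0:9), sprintf("642%d1", 0:9),
             "641", "6430", "64")
  births <- make_birth("m1")
  for (code in codes) {
    hosp <- tibble::tibble(mother_id = "m1",
                           admission_date = births$lmp_date + 30,
                           discharge_date = births$lmp_date + 31,
                           diagnosis_codes = code)
    f <- detect_hypertensive(births, hosp)
    chars <- strsplit(code, "")[[1]]
    expect_equal(f$hypertension,
                 length(chars) >= 3 && paste(chars[1:3], collapse = "") == "642",
                 label = code)
    expect_equal(f$any_preeclampsia_eclampsia,
                 length(chars) >= 4 &&
                   paste(chars[1:3], collapse = "") == "642" &&
                   chars[4] %in% c("4", "5", "6", "7"),
                 label = code)
  }
})

test_that("malformed diagnosis codes are skipped with a warning, not fatal", {
  births <- make_birth("m1")
  hosp <- tibble::tibble(mother_id = "m1",
                         admission_date = births$lmp_date + 30,
                         discharge_date = births$lmp_date + 31,
                         diagnosis_codes = "64?5;6424")
  expect_warning(f <- detect_hypertensive(births, hosp), "malformed")
  expect_true(f$mild_preeclampsia)
})

test_that("derived outcomes satisfy the denominator and implication invariants", {
  cfg <- small_config(seed = 17, n = 600)
  b <- generate_cohort(cfg)
  sel <- select_initial(b$births)
  casc <- apply_cascade(sel$selected, b$episodes, b$concentrations,
                        cfg$pollutants)
  out <- derive_outcomes(casc$analysed, b$hospital, b$growth_table)
  expect_equal(sum(!is.na(out$term_low_birthweight)),
               nrow(out) - sum(out$preterm))
  expect_true(all(out$hypertension[out$any_preeclampsia_eclampsia]))
  expect_true(all(out$any_preeclampsia_eclampsia[out$severe_preeclampsia]))
  expect_true(all(out$any_preeclampsia_eclampsia[out$eclampsia]))
  expect_equal(sum(table(out$weight_for_ga)), nrow(out))
  smry <- summarize_outcomes(casc$analysed, out)
  tot <- smry$categorical[smry$categorical$variable == "preterm" &
                            smry$categorical$city == "Total", ]
  expect_equal(sum(tot$n), nrow(out))
  expect_true(all(smry$categorical$ci_low <= smry$categorical$pct &
                    smry$categorical$pct <= smry$categorical$ci_high))
})
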