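#' Preterm birth
#'
#' A birth before 37 completed gestational weeks (strict inequality).
#'
#' @param gestational_weeks Completed weeks at delivery.
#' @return Logical vector.
#' @export
classify_preterm <- function(gestational_weeks) {
  gestational_weeks < 37
}

#' Term low birthweight
#'
#' Birthweight under 2500 g (strict) among term births only; preterm births
#' get `NA` (the outcome is not defined for them, and they are excluded
#' from its denominator).
#'
#' @param gestational_weeks Completed weeks at delivery.
#' @param birthweight_g Birthweight in grams.
#' @return Logical vector with `NA` for preterm births.
#' @export
classify_term_lbw <- function(gestational_weeks, birthweight_g) {
  ifelse(classify_preterm(gestational_weeks), NA, birthweight_g < 2500)
}

#' Weight for gestational age
#'
#' Classifies birthweight against a reference chart stratified by infant
#' sex, completed gestational week and parity class: `small` below the 10th
#' percentile (strict), `large` above the 90th (strict), `appropriate`
#' otherwise (boundaries included).
#'
#' @param infant_sex,gestational_weeks,parity_class Stratum key vectors.
#' @param birthweight_g Birthweight in grams.
#' @param table Reference table with columns `infant_sex`,
#'   `gestational_week`, `parity_class`, `p10`, `p90`
#'   (see [reference_growth_table()]).
#' @return Character vector in `{small, appropriate, large}`.
#' @export
classify_weight_for_ga <- function(infant_sex, gestational_weeks,
                                   parity_class, birthweight_g,
                                   table = reference_growth_table()) {
  key <- paste(infant_sex, gestational_weeks, parity_class)
  tkey <- paste(table$infant_sex, table$gestational_week, table$parity_class)
  i <- match(key, tkey)
  if (anyNA(i)) {
    bad <- unique(key[is.na(i)])
    stop(sprintf("stratum not in reference table: %s",
                 paste(bad, collapse = "; ")), call. = FALSE)
  }
  ifelse(birthweight_g < table$p10[i], "small",
         ifelse(birthweight_g > table$p90[i], "large", "appropriate"))
}

#' Apgar score class
#'
#' Bands the 5-minute Apgar score: 7-10 normal, 4-6 needs assistance, 1-3
#' needs resuscitation. A score of 0 is routed to an `"unclassified"`
#' bucket rather than silently banded.
#'
#' @param apgar Integer scores 0-10.
#' @return Character vector.
#' @export
classify_apgar <- function(apgar) {
  ifelse(apgar >= 7, "normal",
         ifelse(apgar >= 4, "needs_assistance",
                ifelse(apgar >= 1, "needs_resuscitation", "unclassified")))
}

#' Hypertensive-complication flags from hospital discharges
#'
#' Scans each mother's discharges with an admission date inside the closed
#' pregnancy interval `[lmp, delivery]` for ICD-9 diagnosis codes in the
#' 642 family, stored undotted: `hypertension` for any 642x, and the
#' preeclampsia/eclampsia sub-flags by fourth digit (642.4 mild, 642.5
#' severe, 642.6 eclampsia, 642.4-642.7 any). Matching is by string prefix
#' on the undotted code, so a bare 3-digit "642" sets only the family flag.
#' Codes that are not plain digit strings are skipped with a warning.
#'
#' @param births Tibble with `mother_id`, `lmp_date`, `delivery_date`.
#' @param hospital Tibble with `mother_id`, `admission_date`,
#'   `diagnosis_codes` (one code, or several separated by `;`).
#' @return Tibble per mother: logical `hypertension`, `mild_preeclampsia`,
#'   `severe_preeclampsia`, `eclampsia`, `any_preeclampsia_eclampsia`.
#' @export
detect_hypertensive <- function(births, hospital) {
  flags <- tibble::tibble(
    mother_id = births$mother_id,
    hypertension = FALSE, mild_preeclampsia = FALSE,
    severe_preeclampsia = FALSE, eclampsia = FALSE,
    any_preeclampsia_eclampsia = FALSE)
  if (nrow(hospital) == 0L) return(flags)
  h <- dplyr::inner_join(
    hospital, births[, c("mother_id", "lmp_date", "delivery_date")],
    by = "mother_id")
  h <- h[h$admission_date >= h$lmp_date &
           h$admission_date <= h$delivery_date, , drop = FALSE]
  if (nrow(h) == 0L) return(flags)
  codes <- strsplit(as.character(h$diagnosis_codes), ";", fixed = TRUE)
  mid <- rep(h$mother_id, lengths(codes))
  code <- trimws(unlist(codes))
  bad <- !grepl("^[0-9]+$", code) & !grepl("^V[0-9]+$", code)
  if (any(bad)) {
    warning(sprintf("skipping %d malformed diagnosis code(s): %s",
                    sum(bad), paste(unique(code[bad]), collapse = ", ")))
    mid <- mid[!bad]; code <- code[!bad]
  }
  d4 <- substr(code, 4, 4)
  set_flag <- function(flags, col, hit) {
    flags[[col]] <- flags$mother_id %in% unique(mid[hit])
    flags
  }
  flags <- set_flag(flags, "hypertension", startsWith(code, "642"))
  flags <- set_flag(flags, "mild_preeclampsia", startsWith(code, "6424"))
  flags <- set_flag(flags, "severe_preeclampsia", startsWith(code, "6425"))
  flags <- set_flag(flags, "eclampsia", startsWith(code, "6426"))
  flags <- set_flag(flags, "any_preeclampsia_eclampsia",
                    startsWith(code, "642") & d4 %in% c("4", "5", "6", "7"))
  flags
}

#' Derive all pregnancy outcomes for a cohort
#'
#' @param births Analysed delivery certificates.
#' @param hospital Hospital discharge tibble (optional).
#' @param growth_table Reference chart for weight-for-gestational-age.
#' @return Tibble per birth: `preterm`, `term_low_birthweight` (NA for
#'   preterm), `weight_for_ga`, `apgar_class`, and the hypertensive flags.
#' @export
derive_outcomes <- function(births, hospital = NULL,
                            growth_table = reference_growth_table()) {
  out <- tibble::tibble(
    mother_id = births$mother_id,
    city = births$city,
    preterm = classify_preterm(births$gestational_weeks),
    term_low_birthweight = classify_term_lbw(births$gestational_weeks,
                                             births$birthweight),
    weight_for_ga = classify_weight_for_ga(
      births$infant_sex, births$gestational_weeks, births$parity,
      births$birthweight, growth_table),
    apgar_class = classify_apgar(births$apgar))
  if (!is.null(hospital))
    out <- dplyr::left_join(out, detect_hypertensive(births, hospital),
                            by = "mother_id")
  out
}

#' Outcome summary table
#'
#' Mean (SD) of the continuous birth measures and category counts with
#' percentages and normal-approximation 95% confidence intervals for the
#' derived outcomes, per city and overall.
#'
#' @param births Analysed delivery certificates.
#' @param outcomes Tibble from [derive_outcomes()].
#' @return List with `continuous` and `categorical` tibbles.
#' @export
summarize_outcomes <- function(births, outcomes) {
  b2 <- dplyr::bind_rows(births, dplyr::mutate(births, city = "Total"))
  cont <- b2 |>
    dplyr::group_by(.data$city) |>
    dplyr::summarise(dplyr::across(
      c("gestational_weeks", "birthweight", "length",
        "cranial_circumference"),
      list(mean = ~mean(.x, na.rm = TRUE), sd = ~stats::sd(.x, na.rm = TRUE))),
      .groups = "drop")
  o2 <- dplyr::bind_rows(outcomes, dplyr::mutate(outcomes, city = "Total"))
  cat_one <- function(var) {
    o2 |>
      dplyr::filter(!is.na(.data[[var]])) |>
      dplyr::count(.data$city, value = as.character(.data[[var]])) |>
      dplyr::group_by(.data$city) |>
      dplyr::mutate(variable = var,
                    pct = round_half_up(100 * .data$n / sum(.data$n), 1),
                    ci_low = pmax(0, round_half_up(
                      100 * (.data$n / sum(.data$n) -
                               1.96 * sqrt(.data$n / sum(.data$n) *
                                             (1 - .data$n / sum(.data$n)) /
                                             sum(.data$n))), 1)),
                    ci_high = pmin(100, round_half_up(
                      100 * (.data$n / sum(.data$n) +
                               1.96 * sqrt(.data$n / sum(.data$n) *
                                             (1 - .data$n / sum(.data$n)) /
                                             sum(.data$n))), 1))) |>
      dplyr::ungroup()
  }
  cats <- dplyr::bind_rows(lapply(
    c("preterm", "term_low_birthweight", "weight_for_ga", "apgar_class"),
    cat_one))
  list(continuous = cont,
       categorical = cats[, c("variable", "city", "value", "n", "pct",
                              "ci_low", "ci_high")])
}
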