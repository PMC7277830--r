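#' Percentages over non-missing category counts
#'
#' The denominator convention of the cohort-description tables: percentages
#' are taken over the non-missing records only, rounded half-up to one
#' decimal.
#'
#' @param counts Named integer vector of category counts (missing excluded).
#' @return Named numeric vector of percentages.
#' @export
#' @examples
#' category_percents(c(university = 57065, high_school = 97456,
#'                     junior_high = 42856, primary = 11948))
category_percents <- function(counts) {
  round_half_up(100 * counts / sum(counts), 1)
}

#' Categorical cohort summary
#'
#' Counts and percentages of a maternal/birth categorical variable, per city
#' and overall; missing values are excluded from the denominators and
#' reported separately.
#'
#' @param cohort Analysed delivery certificates.
#' @param variable Name of a categorical column.
#' @return Tibble `variable`, `city`, `category`, `n`, `pct`, plus an
#'   `n_missing` attribute table.
#' @export
summarize_categorical <- function(cohort, variable) {
  if (!variable %in% names(cohort))
    stop(sprintf("unknown variable `%s`", variable), call. = FALSE)
  c2 <- dplyr::bind_rows(cohort, dplyr::mutate(cohort, city = "Total"))
  miss <- c2 |>
    dplyr::group_by(.data$city) |>
    dplyr::summarise(n_missing = sum(is.na(.data[[variable]])),
                     .groups = "drop")
  out <- c2 |>
    dplyr::filter(!is.na(.data[[variable]])) |>
    dplyr::count(.data$city, category = .data[[variable]]) |>
    dplyr::group_by(.data$city) |>
    dplyr::mutate(pct = category_percents(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::mutate(variable = variable) |>
    dplyr::select("variable", "city", "category", "n", "pct")
  attr(out, "n_missing") <- miss
  out
}

#' Employed-vs-not-employed contrast
#'
#' Collapses maternal occupation into the binary contrast used for the
#' exposure crosstabs: employed vs not employed (unemployed, looking for the
#' first job, housewives); students and "other" are excluded from the
#' contrast.
#'
#' @param occupation Character vector of occupation categories.
#' @return Character vector in `{employed, not_employed, excluded}` (`NA`
#'   stays `NA`).
#' @export
occupation_binary <- function(occupation) {
  dplyr::case_match(
    occupation,
    "employed" ~ "employed",
    c("unemployed", "looking_first_job", "housewife") ~ "not_employed",
    c("student", "other") ~ "excluded",
    NA ~ NA_character_
  )
}

#' High-exposure prevalence by socioeconomic indicator
#'
#' For one pollutant, flags women whose whole-pregnancy standard exposure
#' exceeds the 75th percentile of the exposure distribution (type-7 quantile;
#' strict `>`), the percentile being computed within city by default or over
#' the pooled cohort with `scope = "pooled"`, and tabulates the prevalence
#' of that flag by the categories of a socioeconomic indicator. Wilson 95%
#' confidence bounds accompany each prevalence.
#'
#' @param cohort Analysed delivery certificates; for
#'   `ses_indicator = "deprivation_quintile"` it must carry a
#'   `deprivation_quintile` column (see [link_deprivation()]).
#' @param profiles Tibble from [exposure_profiles()].
#' @param pollutant Pollutant to tabulate.
#' @param ses_indicator One of `education`, `occupation_binary`,
#'   `citizenship`, `deprivation_quintile`.
#' @param scope `"city"` (default) or `"pooled"` percentile scope.
#' @return Tibble `city`, `pollutant`, `ses_indicator`, `category`, `n`,
#'   `n_high`, `prevalence`, `ci_low`, `ci_high`, `threshold`. Categories
#'   with empty denominators are kept with `NA` prevalence.
#' @export
high_exposure_crosstab <- function(cohort, profiles, pollutant,
                                   ses_indicator = c("education",
                                                     "occupation_binary",
                                                     "citizenship",
                                                     "deprivation_quintile"),
                                   scope = c("city", "pooled")) {
  ses_indicator <- match.arg(ses_indicator)
  scope <- match.arg(scope)
  pr <- profiles[profiles$pollutant == pollutant,
                 c("mother_id", "standard_exposure")]
  d <- dplyr::inner_join(cohort, pr, by = "mother_id")
  d$ses <- switch(ses_indicator,
                  education = d$education,
                  occupation_binary = occupation_binary(d$occupation),
                  citizenship = d$citizenship,
                  deprivation_quintile = as.character(d$deprivation_quintile))
  if (ses_indicator == "occupation_binary")
    d$ses[d$ses == "excluded"] <- NA_character_
  if (scope == "pooled") {
    thr_tab <- tibble::tibble(
      city = unique(d$city),
      threshold = stats::quantile(d$standard_exposure, 0.75, type = 7,
                                  names = FALSE))
  } else {
    thr_tab <- d |>
      dplyr::group_by(.data$city) |>
      dplyr::summarise(threshold = stats::quantile(
        .data$standard_exposure, 0.75, type = 7, names = FALSE),
        .groups = "drop")
  }
  d <- dplyr::left_join(d, thr_tab, by = "city")
  d$high <- d$standard_exposure > d$threshold
  out <- d |>
    dplyr::filter(!is.na(.data$ses)) |>
    dplyr::group_by(.data$city, category = .data$ses) |>
    dplyr::summarise(n = dplyr::n(), n_high = sum(.data$high),
                     threshold = .data$threshold[1], .groups = "drop")
  out$prevalence <- ifelse(out$n > 0, out$n_high / out$n, NA_real_)
  wil <- .wilson_ci(out$n_high, out$n)
  out$ci_low <- wil$low
  out$ci_high <- wil$high
  out$pollutant <- pollutant
  out$ses_indicator <- ses_indicator
  out[, c("city", "pollutant", "ses_indicator", "category", "n", "n_high",
          "prevalence", "ci_low", "ci_high", "threshold")]
}

.wilson_ci <- function(x, n, z = 1.96) {
  p <- ifelse(n > 0, x / n, NA_real_)
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  list(low = pmax(0, centre - half), high = pmin(1, centre + half))
}

#' Mean back-extrapolated exposure by season of conception and trimester
#'
#' Reproduces the seasonal exposure pattern check: mean back-extrapolated
#' trimester exposures per season of conception and pollutant, over women
#' with back-extrapolation available.
#'
#' @param profiles Tibble from [exposure_profiles()].
#' @return Tibble `pollutant`, `season_of_conception`, `trimester`,
#'   `mean_exposure`, `n`.
#' @export
exposure_season_summary <- function(profiles) {
  profiles |>
    dplyr::filter(.data$back_available) |>
    dplyr::select("pollutant", "season_of_conception",
                  t1 = "back_trimester1", t2 = "back_trimester2",
                  t3 = "back_trimester3") |>
    tidyr::pivot_longer(c("t1", "t2", "t3"), names_to = "trimester",
                        values_to = "exposure") |>
    dplyr::filter(!is.na(.data$exposure)) |>
    dplyr::group_by(.data$pollutant, .data$season_of_conception,
                    .data$trimester) |>
    dplyr::summarise(mean_exposure = mean(.data$exposure), n = dplyr::n(),
                     .groups = "drop")
}

#' Attach deprivation quintiles to a cohort
#'
#' Links each birth to the census block of the mother's residence at
#' delivery (her address on the day before delivery) and carries over that
#' block's deprivation quintile and score.
#'
#' @param cohort Analysed delivery certificates.
#' @param episodes Residence episodes.
#' @param index Tibble from [deprivation_index()].
#' @return `cohort` with `census_block_id`, `deprivation_score` and
#'   `deprivation_quintile` columns.
#' @export
link_deprivation <- function(cohort, episodes, index) {
  ep <- dplyr::inner_join(
    episodes, cohort[, c("mother_id", "delivery_date")], by = "mother_id")
  at_del <- ep[ep$start_date <= ep$delivery_date - 1L &
                 ep$end_date >= ep$delivery_date, ,
               drop = FALSE]
  # fall back to the last pregnancy address if the delivery-eve day is
  # uncovered (tolerated gaps)
  last_ep <- ep |>
    dplyr::group_by(.data$mother_id) |>
    dplyr::slice_max(.data$start_date, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  pick <- dplyr::bind_rows(at_del, last_ep) |>
    dplyr::distinct(.data$mother_id, .keep_all = TRUE)
  cohort$census_block_id <- pick$census_block_id[
    match(cohort$mother_id, pick$mother_id)]
  i <- match(cohort$census_block_id, index$block_id)
  cohort$deprivation_score <- index$score[i]
  cohort$deprivation_quintile <- index$quintile[i]
  cohort
}

#' Bar chart of high-exposure prevalence by SES category
#'
#' @param crosstab Tibble from [high_exposure_crosstab()].
#' @return A ggplot object, faceted by city.
#' @export
plot_high_exposure <- function(crosstab) {
  ggplot2::ggplot(crosstab,
                  ggplot2::aes(x = .data$category, y = .data$prevalence)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_low,
                                        ymax = .data$ci_high), width = 0.2) +
    ggplot2::facet_wrap(~city) +
    ggplot2::labs(
      x = unique(crosstab$ses_indicator),
      y = "prevalence of exposure > 75th percentile",
      title = sprintf("High %s exposure by %s", unique(crosstab$pollutant),
                      unique(crosstab$ses_indicator))) +
    ggplot2::theme_minimal()
}
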