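#' Exposure profiles for a cohort
#'
#' Computes, for every mother and pollutant, the residence-time-weighted
#' standard exposure over the whole pregnancy and the back-extrapolated
#' (daily-ratio-adjusted) mean over each pregnancy window: whole pregnancy,
#' trimesters 1-3, first five months, last week. Back-extrapolation is
#' attributed only to births in `backextrap_years` (2008-2013 by default, so
#' every pregnancy has full monitor coverage from 2007 onwards); other
#' births, and windows falling into monitor gaps longer than
#' `max_gap_days`, carry `NA` with `back_available = FALSE`.
#'
#' @param births Analysed delivery certificates (needs `mother_id`, `city`,
#'   `lmp_date`, `delivery_date`).
#' @param episodes Residence episodes.
#' @param concentrations Tibble `address_id`, `pollutant`, `annual_conc`.
#' @param monitors Daily monitor tibble `city`, `pollutant`, `date`, `value`.
#' @param pollutants Pollutants to evaluate (default: all in
#'   `concentrations`).
#' @param lur_period,max_gap_days Passed to [compute_mlur()] /
#'   [daily_ratio_series()].
#' @param mode `"daily_address"`: each day contributes the concentration of
#'   the address occupied that day; `"constant_weights"`: each day
#'   contributes the pregnancy-constant residence-weighted concentration.
#' @param backextrap_years Inclusive delivery-year range eligible for
#'   back-extrapolation.
#' @return Tibble with one row per mother x pollutant: `standard_exposure`,
#'   `back_whole`, `back_trimester1..3`, `back_first_five_months`,
#'   `back_last_week`, `back_available`, `season_of_conception`.
#' @export
exposure_profiles <- function(births, episodes, concentrations, monitors,
                              pollutants = NULL, lur_period = NULL,
                              max_gap_days = 7,
                              mode = c("daily_address", "constant_weights"),
                              backextrap_years = c(2008L, 2013L)) {
  mode <- match.arg(mode)
  if (is.null(pollutants)) pollutants <- unique(concentrations$pollutant)

  # clip episodes to each mother's pregnancy
  ep <- dplyr::inner_join(
    episodes,
    births[, c("mother_id", "lmp_date", "delivery_date")],
    by = "mother_id")
  ep$s <- pmax(as.integer(ep$start_date), as.integer(ep$lmp_date))
  ep$e <- pmin(as.integer(ep$end_date), as.integer(ep$delivery_date))
  ep <- ep[ep$s < ep$e, c("mother_id", "address_id", "s", "e")]
  ep$days <- ep$e - ep$s

  base <- tibble::tibble(
    mother_id = births$mother_id, city = births$city,
    lmp = as.integer(births$lmp_date),
    gest = as.integer(births$delivery_date - births$lmp_date),
    year = as.integer(format(births$delivery_date, "%Y")),
    season_of_conception = .season_of_month(
      as.integer(format(births$lmp_date, "%m"))))
  eligible <- base$year >= backextrap_years[1] & base$year <= backextrap_years[2]

  # day expansion once; pollutant-specific joins in the loop below
  edt <- data.table::as.data.table(ep)
  ddt <- edt[, list(day = seq.int(s, e - 1L)),
             by = c("mother_id", "address_id", "s")]
  ddt[, s := NULL]
  bdt <- data.table::as.data.table(base[, c("mother_id", "city", "lmp", "gest")])
  ddt <- merge(ddt, bdt, by = "mother_id")
  ddt[, off := day - lmp]

  out <- list()
  for (p in pollutants) {
    cc <- concentrations[concentrations$pollutant == p, ]
    # standard exposure: weighted mean of annual concentrations
    ci <- cc$annual_conc[match(ep$address_id, cc$address_id)]
    if (anyNA(ci)) {
      bad <- unique(ep$mother_id[is.na(ci)])
      stop(sprintf("missing %s concentration for %d mother(s) (e.g. %s); run the selection cascade first",
                   p, length(bad), bad[1]), call. = FALSE)
    }
    std <- tibble::tibble(mother_id = ep$mother_id, wc = ep$days * ci,
                          days = ep$days) |>
      dplyr::group_by(.data$mother_id) |>
      dplyr::summarise(standard_exposure = sum(.data$wc) / sum(.data$days),
                       .groups = "drop")

    # per-city ratio grids
    ratio_by_city <- lapply(split(
      monitors[monitors$pollutant == p, ],
      monitors$city[monitors$pollutant == p]), function(srs) {
        rs <- daily_ratio_series(srs[order(srs$date), ],
                                 lur_period = lur_period,
                                 max_gap_days = max_gap_days)
        stats::setNames(rs$ratio, as.integer(rs$date))
      })

    dd <- ddt[ddt$mother_id %in% base$mother_id[eligible], ]
    dd$conc <- cc$annual_conc[match(dd$address_id, cc$address_id)]
    dd$ratio <- NA_real_
    for (ct in names(ratio_by_city)) {
      sel <- dd$city == ct
      dd$ratio[sel] <- ratio_by_city[[ct]][as.character(dd$day[sel])]
    }
    if (mode == "constant_weights")
      dd$conc <- std$standard_exposure[match(dd$mother_id, std$mother_id)]
    dd[, v := conc * ratio]
    nan2na <- function(x) ifelse(is.nan(x), NA_real_, x)
    agg <- dd[, list(
      back_whole = mean(v),
      back_trimester1 = mean(v[off < 90L]),
      back_trimester2 = mean(v[off >= 90L & off < 180L]),
      back_trimester3 = nan2na(mean(v[off >= 180L])),
      back_first_five_months = mean(v[off < 150L]),
      back_last_week = mean(v[off >= gest[1] - 7L])
    ), by = "mother_id"]

    res <- dplyr::left_join(dplyr::left_join(base, std, by = "mother_id"),
                            tibble::as_tibble(agg), by = "mother_id")
    res$pollutant <- p
    res$back_available <- eligible & !is.na(res$back_whole)
    out[[p]] <- res
  }
  dplyr::bind_rows(out)[, c(
    "mother_id", "city", "pollutant", "season_of_conception",
    "standard_exposure", "back_whole", "back_trimester1", "back_trimester2",
    "back_trimester3", "back_first_five_months", "back_last_week",
    "back_available")]
}
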