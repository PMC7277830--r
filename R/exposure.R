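#' Pregnancy exposure windows
#'
#' Builds the half-open, day-resolution windows used for exposure averaging.
#' Day 0 is the date of the last menstrual period (LMP); the whole window is
#' `[lmp, delivery)`. Trimesters cut at days 90 and 180 (trimester 3 runs to
#' delivery), the first five months are days 0-149, and the last week is the
#' final 7 days before delivery. Season of conception follows the LMP month
#' (Dec-Feb winter, Mar-May spring, Jun-Aug summer, Sep-Nov autumn).
#'
#' @param lmp_date,delivery_date Dates; `lmp_date` must precede
#'   `delivery_date`.
#' @return A list of class `cohortair_windows`: each window is a length-2
#'   Date vector `[start, end)`; plus `season_of_conception`,
#'   `gestation_days`, `valid` (gestation within 154-315 days; out-of-range
#'   pregnancies are flagged for the reject log, not errored) and `flags`
#'   (e.g. `"trimester3_empty"` for gestations under 180 days).
#' @export
#' @examples
#' w <- build_windows(as.Date("2010-01-15"), as.Date("2010-10-15"))
#' w$trimester1; w$season_of_conception
build_windows <- function(lmp_date, delivery_date) {
  if (lmp_date >= delivery_date)
    stop("lmp_date must precede delivery_date", call. = FALSE)
  len <- .days_in(lmp_date, delivery_date)
  clip <- function(a, b) c(min(lmp_date + a, delivery_date),
                           min(lmp_date + b, delivery_date))
  flags <- character()
  if (len <= 180L) flags <- c(flags, "trimester3_empty")
  w <- list(
    whole = c(lmp_date, delivery_date),
    trimester1 = clip(0L, 90L),
    trimester2 = clip(90L, 180L),
    trimester3 = clip(180L, len),
    first_five_months = clip(0L, 150L),
    last_week = c(delivery_date - 7L, delivery_date),
    season_of_conception = .season_of_month(
      as.integer(format(lmp_date, "%m"))),
    gestation_days = len,
    valid = len >= 154L && len <= 315L,
    flags = flags
  )
  class(w) <- "cohortair_windows"
  w
}

#' Residence-time weights over a window
#'
#' For each address, the fraction of the window's days the mother spent
#' there. With full coverage the weights are days-at-address over window
#' length and sum to one; when a tolerated gap is present the weights are
#' renormalised over the covered days so they still sum to one.
#'
#' @param episodes Episode tibble for one mother (columns `address_id`,
#'   `start_date`, `end_date`).
#' @param window Length-2 Date vector `[start, end)`.
#' @param tolerance_days Maximum total uncovered days before erroring.
#' @return Tibble `address_id`, `days`, `weight`.
#' @export
residence_weights <- function(episodes, window, tolerance_days = 0) {
  len <- .days_in(window[1], window[2])
  s <- pmax(as.integer(episodes$start_date), as.integer(window[1]))
  e <- pmin(as.integer(episodes$end_date), as.integer(window[2]))
  keep <- s < e
  d <- tibble::tibble(address_id = episodes$address_id[keep],
                      days = (e - s)[keep]) |>
    dplyr::group_by(.data$address_id) |>
    dplyr::summarise(days = sum(.data$days), .groups = "drop")
  covered <- sum(d$days)
  if (len - covered > tolerance_days)
    stop(sprintf("window has %d uncovered day(s), tolerance %d",
                 len - covered, tolerance_days), call. = FALSE)
  d$weight <- d$days / covered
  d
}

#' Residence-weighted exposure from modelled annual concentrations
#'
#' The standard (non-extrapolated) exposure: the weighted mean of the
#' modelled annual concentration at each of the mother's addresses, weights
#' from [residence_weights()].
#'
#' @param weights Tibble from [residence_weights()].
#' @param concentrations Tibble `address_id`, `pollutant`, `annual_conc`.
#' @param pollutant Pollutant to evaluate.
#' @return Exposure in ug/m3.
#' @export
standard_exposure <- function(weights, concentrations, pollutant) {
  cc <- concentrations[concentrations$pollutant == pollutant, ]
  idx <- match(weights$address_id, cc$address_id)
  if (anyNA(idx))
    stop(sprintf("missing %s concentration for address(es): %s", pollutant,
                 paste(weights$address_id[is.na(idx)], collapse = ", ")),
         call. = FALSE)
  sum(weights$weight * cc$annual_conc[idx])
}

#' Monitor mean over the LUR campaign period
#'
#' The arithmetic mean of the daily background concentration over the
#' land-use-regression measurement period (calendar year 2010 by default).
#' Up to 10% of the period's days may be missing, in which case the mean of
#' the available days is used and a message is emitted; more than 10%
#' missing is an error.
#'
#' @param series Tibble `date`, `value` for one city and pollutant.
#' @param lur_period Length-2 Date vector, inclusive; default the 2010
#'   calendar year.
#' @return The campaign-period mean.
#' @export
compute_mlur <- function(series, lur_period = NULL) {
  if (is.null(lur_period))
    lur_period <- as.Date(c("2010-01-01", "2010-12-31"))
  all_days <- seq(lur_period[1], lur_period[2], by = "day")
  x <- series$value[match(all_days, series$date)]
  n_miss <- sum(is.na(x))
  if (n_miss > 0.10 * length(all_days))
    stop(sprintf("%d of %d campaign-period days missing from monitor series",
                 n_miss, length(all_days)), call. = FALSE)
  if (n_miss > 0)
    message(sprintf("campaign mean computed over %d of %d days (%d missing)",
                    length(all_days) - n_miss, length(all_days), n_miss))
  mean(x, na.rm = TRUE)
}

#' Daily concentration-to-campaign ratio series
#'
#' The temporal adjustment factor of back-extrapolation: each day's
#' background concentration divided by the campaign-period mean. Missing
#' days inside the series are filled by linear interpolation between the
#' nearest observed flanking days, for gaps of at most `max_gap_days`;
#' longer gaps leave `NA` and are reported by [daily_ratio()].
#'
#' @param series Tibble `date`, `value` for one city and pollutant.
#' @param m_lur Campaign mean; computed by [compute_mlur()] if `NULL`.
#' @param lur_period Passed to [compute_mlur()].
#' @param max_gap_days Longest interior gap to interpolate (default 7).
#' @return Tibble `date`, `dc`, `ratio` on the full daily grid of the
#'   series' date range.
#' @export
daily_ratio_series <- function(series, m_lur = NULL, lur_period = NULL,
                               max_gap_days = 7) {
  if (is.null(m_lur)) m_lur <- compute_mlur(series, lur_period)
  if (m_lur <= 0) stop("campaign mean must be positive", call. = FALSE)
  grid <- seq(min(series$date), max(series$date), by = "day")
  dc <- series$value[match(grid, series$date)]
  if (anyNA(dc)) {
    filled <- stats::approx(as.integer(grid)[!is.na(dc)], dc[!is.na(dc)],
                            xout = as.integer(grid))$y
    r <- rle(is.na(dc))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in which(r$values & r$lengths <= max_gap_days))
      dc[starts[i]:ends[i]] <- filled[starts[i]:ends[i]]
  }
  tibble::tibble(date = grid, dc = dc, ratio = dc / m_lur)
}

#' Daily ratio at given dates
#'
#' @param series Tibble `date`, `value` for one city and pollutant.
#' @param dates Dates at which the ratio is needed.
#' @param m_lur,lur_period,max_gap_days See [daily_ratio_series()].
#' @return Numeric ratio per date; errors (identifying the date range) if a
#'   requested date falls in a gap longer than `max_gap_days` or outside the
#'   series.
#' @export
daily_ratio <- function(series, dates, m_lur = NULL, lur_period = NULL,
                        max_gap_days = 7) {
  rs <- daily_ratio_series(series, m_lur, lur_period, max_gap_days)
  r <- rs$ratio[match(dates, rs$date)]
  if (anyNA(r)) {
    bad <- dates[is.na(r)]
    stop(sprintf("no monitor ratio available for %s .. %s (gap > %d days or outside series)",
                 min(bad), max(bad), max_gap_days), call. = FALSE)
  }
  r
}

#' Back-extrapolated window exposure for one mother
#'
#' Averages, over the days of a window, the modelled annual concentration of
#' the address occupied on each day multiplied by that day's
#' monitor-to-campaign ratio. With `mode = "constant_weights"` the
#' residence-weighted whole-pregnancy concentration is used on every day
#' instead of the address-of-day value, so moves no longer interact with the
#' temporal term.
#'
#' @param episodes Episode tibble for one mother.
#' @param concentrations Tibble `address_id`, `pollutant`, `annual_conc`.
#' @param ratio Tibble `date`, `ratio` from [daily_ratio_series()].
#' @param window Length-2 Date vector `[start, end)`.
#' @param pollutant Pollutant to evaluate.
#' @param mode `"daily_address"` (default) or `"constant_weights"`.
#' @param whole_window Whole-pregnancy window, only used for the constant
#'   weights of `mode = "constant_weights"`; defaults to `window`.
#' @return Mean extrapolated concentration over the window (ug/m3).
#' @export
back_extrapolate <- function(episodes, concentrations, ratio, window,
                             pollutant,
                             mode = c("daily_address", "constant_weights"),
                             whole_window = NULL) {
  mode <- match.arg(mode)
  days <- seq(window[1], window[2] - 1L, by = "day")
  r <- ratio$ratio[match(days, ratio$date)]
  if (anyNA(r))
    stop(sprintf("monitor ratio unavailable within window %s .. %s",
                 window[1], window[2]), call. = FALSE)
  if (mode == "constant_weights") {
    if (is.null(whole_window)) whole_window <- window
    w <- residence_weights(episodes, whole_window)
    return(standard_exposure(w, concentrations, pollutant) * mean(r))
  }
  addr <- .address_on_day(episodes, days)
  if (anyNA(addr))
    stop("window day(s) not covered by any residence episode", call. = FALSE)
  cc <- concentrations[concentrations$pollutant == pollutant, ]
  ci <- cc$annual_conc[match(addr, cc$address_id)]
  if (anyNA(ci))
    stop(sprintf("missing %s concentration for address(es): %s", pollutant,
                 paste(unique(addr[is.na(ci)]), collapse = ", ")),
         call. = FALSE)
  mean(ci * r)
}

# address occupied on each day (NA where uncovered); later episodes win on
# (unexpected) overlap
.address_on_day <- function(episodes, days) {
  out <- rep(NA_character_, length(days))
  o <- order(episodes$start_date)
  for (i in o) {
    hit <- days >= episodes$start_date[i] & days < episodes$end_date[i]
    out[hit] <- episodes$address_id[i]
  }
  out
}

#' Exposure summary by city
#'
#' Arithmetic mean and sample standard deviation (denominator n-1) of the
#' whole-pregnancy standard exposure over women, per city and pollutant.
#'
#' @param profiles Tibble from [exposure_profiles()].
#' @return Tibble `city`, `pollutant`, `n`, `mean`, `sd`.
#' @export
exposure_summary <- function(profiles) {
  profiles |>
    dplyr::group_by(.data$city, .data$pollutant) |>
    dplyr::summarise(n = dplyr::n(),
                     mean = mean(.data$standard_exposure),
                     sd = stats::sd(.data$standard_exposure),
                     .groups = "drop")
}
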