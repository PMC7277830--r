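#' Demographic selection of delivery certificates
#'
#' Keeps singleton livebirths from women aged 15-49 years (inclusive) at
#' delivery, optionally restricted to a delivery-year range. Records whose
#' singleton or livebirth flag is missing are routed to a reject log, never
#' silently dropped. Residence coverage is asserted later by the cascade.
#'
#' @param records Tibble of delivery certificates (see [generate_cohort()]).
#' @param year_range Optional inclusive pair of delivery years.
#' @return A list with `selected` and `rejected` tibbles; `rejected` carries
#'   a `reject_reason` column.
#' @export
select_initial <- function(records, year_range = NULL) {
  flag_missing <- is.na(records$singleton) | is.na(records$livebirth)
  rejected <- records[flag_missing, , drop = FALSE]
  if (nrow(rejected)) rejected$reject_reason <- "missing singleton/livebirth flag"
  keep <- records[!flag_missing, , drop = FALSE]
  ok <- keep$singleton & keep$livebirth &
    !is.na(keep$maternal_age) & keep$maternal_age >= 15 & keep$maternal_age <= 49
  if (!is.null(year_range)) {
    yr <- as.integer(format(keep$delivery_date, "%Y"))
    ok <- ok & yr >= year_range[1] & yr <= year_range[2]
  }
  list(selected = keep[ok, , drop = FALSE],
       rejected = tibble::as_tibble(rejected))
}

#' Whole-pregnancy residence coverage
#'
#' Tests whether the union of a mother's in-city residence episodes covers
#' every day of the half-open pregnancy interval `[lmp, delivery)`, allowing
#' a total gap of at most `tolerance_days`.
#'
#' @param record One-row tibble (or list) with `lmp_date`, `delivery_date`,
#'   `city` and `mother_id`.
#' @param episodes Episode tibble for any set of mothers.
#' @param tolerance_days Maximum total number of uncovered days (default 0).
#' @return `TRUE` or `FALSE`. A mother with no episodes at all returns
#'   `FALSE` (counted downstream under the missing-geocoding class).
#' @export
coverage_filter <- function(record, episodes, tolerance_days = 0) {
  ep <- episodes[episodes$mother_id == record$mother_id &
                   episodes$city == record$city, , drop = FALSE]
  if (nrow(ep) == 0L) return(FALSE)
  covered <- .covered_days(ep$start_date, ep$end_date,
                           record$lmp_date, record$delivery_date)
  gap <- .days_in(record$lmp_date, record$delivery_date) - covered
  gap <= tolerance_days
}

# days of [ws, we) covered by the union of [start_i, end_i); intervals may
# abut or overlap
.covered_days <- function(start, end, ws, we) {
  s <- pmax(as.integer(start), as.integer(ws))
  e <- pmin(as.integer(end), as.integer(we))
  keep <- s < e
  if (!any(keep)) return(0L)
  s <- s[keep]; e <- e[keep]
  o <- order(s)
  s <- s[o]; e <- e[o]
  tot <- 0L; cur_s <- s[1]; cur_e <- e[1]
  for (i in seq_along(s)[-1]) {
    if (s[i] > cur_e) {
      tot <- tot + (cur_e - cur_s)
      cur_s <- s[i]; cur_e <- e[i]
    } else cur_e <- max(cur_e, e[i])
  }
  tot + (cur_e - cur_s)
}

# vectorised per-mother covered-day counts for the cascade
.coverage_by_mother <- function(records, episodes) {
  ep <- dplyr::inner_join(
    episodes,
    records[, c("mother_id", "city", "lmp_date", "delivery_date")],
    by = c("mother_id", "city"))
  if (nrow(ep)) {
    ep$s <- pmax(as.integer(ep$start_date), as.integer(ep$lmp_date))
    ep$e <- pmin(as.integer(ep$end_date), as.integer(ep$delivery_date))
    ep <- ep[ep$s < ep$e, , drop = FALSE]
  }
  if (nrow(ep) == 0L) {
    return(stats::setNames(integer(nrow(records)), records$mother_id))
  }
  dt <- data.table::as.data.table(ep[, c("mother_id", "s", "e")])
  data.table::setorder(dt, mother_id, s)
  cov <- dt[, {
    cum_e <- cummax(e)
    gap_prev <- c(0L, pmax(s[-1] - cum_e[-.N], 0L))
    # union length = span minus interior gaps
    list(covered = (max(cum_e) - s[1]) - sum(gap_prev))
  }, by = mother_id]
  out <- stats::setNames(integer(nrow(records)), records$mother_id)
  out[cov$mother_id] <- cov$covered
  out
}

#' Derived audit columns from raw selection counts
#'
#' Computes the analysed counts and printed percentages implied by the
#' per-city initial and exclusion counts of a selection audit, applying the
#' registry tables' conventions: percentages are rounded half-up to one
#' decimal, and the linkage-success row is the complement of the *rounded*
#' geocoding and exposure exclusion percentages (`pct_linkage`), alongside
#' the exact count-based version (`pct_linkage_exact`). A pooled `Total` row
#' is appended.
#'
#' @param counts Tibble with columns `city`, `n_initial`,
#'   `n_missing_geocoding`, `n_missing_exposure`, `n_malformation`,
#'   `n_missing_outcome`.
#' @return Tibble with the input columns plus `n_analysed` and percentage
#'   columns.
#' @export
audit_from_counts <- function(counts) {
  stopifnot(all(c("city", "n_initial", "n_missing_geocoding",
                  "n_missing_exposure", "n_malformation",
                  "n_missing_outcome") %in% names(counts)))
  total <- tibble::tibble(
    city = "Total",
    n_initial = sum(counts$n_initial),
    n_missing_geocoding = sum(counts$n_missing_geocoding),
    n_missing_exposure = sum(counts$n_missing_exposure),
    n_malformation = sum(counts$n_malformation),
    n_missing_outcome = sum(counts$n_missing_outcome))
  a <- dplyr::bind_rows(counts[, names(total)], total)
  a$n_analysed <- a$n_initial - a$n_missing_geocoding - a$n_missing_exposure -
    a$n_malformation - a$n_missing_outcome
  pct <- function(x) round_half_up(100 * x / a$n_initial, 1)
  a$pct_missing_geocoding <- pct(a$n_missing_geocoding)
  a$pct_missing_exposure <- pct(a$n_missing_exposure)
  a$pct_malformation <- pct(a$n_malformation)
  a$pct_missing_outcome <- pct(a$n_missing_outcome)
  a$pct_linkage <- round_half_up(
    100 - a$pct_missing_geocoding - a$pct_missing_exposure, 1)
  a$pct_linkage_exact <- round_half_up(
    100 * (a$n_initial - a$n_missing_geocoding - a$n_missing_exposure) /
      a$n_initial, 1)
  a$pct_of_initial <- pct(a$n_analysed)
  a
}

#' Apply the sequential selection cascade
#'
#' Excludes records in the fixed order (1) missing geocoding — no in-city
#' residence episodes covering the whole pregnancy, (2) missing exposure —
#' a pregnancy address without a modelled concentration for some required
#' pollutant, (3) malformation at birth, (4) missing outcome fields
#' (birthweight, gestational age, infant sex or parity). Each record is
#' counted once, at its first failing step, so the audit telescopes:
#' exclusions plus analysed equal the initial count in every city.
#'
#' @param records Tibble from [select_initial()]'s `selected`.
#' @param episodes Residence-episode tibble.
#' @param concentrations Address-concentration tibble
#'   (`address_id`, `pollutant`, `annual_conc`).
#' @param pollutants Pollutants whose exposure must be computable; defaults
#'   to all pollutants present in `concentrations`.
#' @param tolerance_days Coverage tolerance passed to the geocoding step.
#' @return A list with `analysed` (surviving records, with an
#'   `exclusion` column equal to `"none"`), `excluded` (the rest, labelled),
#'   `audit` (per-city + Total, see [audit_from_counts()]) and
#'   `audit_years` (per-city analysed counts by delivery year).
#' @export
apply_cascade <- function(records, episodes, concentrations,
                          pollutants = NULL, tolerance_days = 0) {
  if (anyDuplicated(records[, c("mother_id", "delivery_date")]))
    stop("registry integrity: duplicate mother_id x delivery_date", call. = FALSE)
  if (is.null(pollutants)) pollutants <- unique(concentrations$pollutant)

  n <- nrow(records)
  exclusion <- rep("none", n)

  # (1) missing geocoding: pregnancy days not covered by in-city episodes
  if (n) {
    covered <- .coverage_by_mother(records, episodes)
    gap <- .days_in(records$lmp_date, records$delivery_date) -
      covered[records$mother_id]
    exclusion[gap > tolerance_days] <- "missing_geocoding"
  }

  # (2) missing exposure: some pregnancy address lacks some pollutant
  open <- exclusion == "none"
  if (any(open)) {
    ep <- dplyr::inner_join(
      episodes, records[open, c("mother_id", "city", "lmp_date",
                                "delivery_date")],
      by = c("mother_id", "city"))
    ep <- ep[as.integer(ep$start_date) < as.integer(ep$delivery_date) &
               as.integer(ep$end_date) > as.integer(ep$lmp_date), ,
             drop = FALSE]
    have <- concentrations[concentrations$pollutant %in% pollutants, ]
    cnt <- table(have$address_id)
    ok_addr <- names(cnt)[cnt == length(pollutants)]
    bad_m <- unique(ep$mother_id[!(ep$address_id %in% ok_addr)])
    exclusion[open & records$mother_id %in% bad_m] <- "missing_exposure"
  }

  # (3) malformations at birth
  open <- exclusion == "none"
  exclusion[open & !is.na(records$malformation) & records$malformation] <-
    "malformation"

  # (4) missing outcomes: birthweight, gestational age, infant sex, parity
  open <- exclusion == "none"
  miss_out <- is.na(records$birthweight) | is.na(records$gestational_weeks) |
    is.na(records$infant_sex) | is.na(records$parity)
  exclusion[open & miss_out] <- "missing_outcome"

  records$exclusion <- exclusion
  counts <- records |>
    dplyr::group_by(.data$city) |>
    dplyr::summarise(
      n_initial = dplyr::n(),
      n_missing_geocoding = sum(.data$exclusion == "missing_geocoding"),
      n_missing_exposure = sum(.data$exclusion == "missing_exposure"),
      n_malformation = sum(.data$exclusion == "malformation"),
      n_missing_outcome = sum(.data$exclusion == "missing_outcome"),
      .groups = "drop") |>
    dplyr::rename(city = "city")
  audit <- audit_from_counts(counts)

  analysed <- records[records$exclusion == "none", , drop = FALSE]
  audit_years <- analysed |>
    dplyr::mutate(year = as.integer(format(.data$delivery_date, "%Y"))) |>
    dplyr::count(.data$city, .data$year, name = "n_analysed")

  list(analysed = analysed,
       excluded = records[records$exclusion != "none", , drop = FALSE],
       audit = audit, audit_years = audit_years)
}

#' Render a selection audit as aligned text
#'
#' Human-readable layout mirroring the per-city selection table: initial
#' counts, the four exclusion rows with percentages, the linkage-success
#' row, analysed counts and percent of the initial dataset.
#'
#' @param audit Tibble from [audit_from_counts()] / [apply_cascade()].
#' @return Character vector of lines, invisibly printable with `cat()`.
#' @export
format_audit <- function(audit) {
  fmt_n <- function(x) formatC(x, format = "d", big.mark = ",")
  row <- function(label, vals) sprintf("%-28s %s", label,
                                       paste(formatC(vals, width = 12),
                                             collapse = " "))
  lines <- c(
    row("", audit$city),
    row("N singleton livebirths", fmt_n(audit$n_initial)),
    row("  missing geocoding",
        sprintf("%s (%.1f%%)", fmt_n(audit$n_missing_geocoding),
                audit$pct_missing_geocoding)),
    row("  missing exposure",
        sprintf("%s (%.1f%%)", fmt_n(audit$n_missing_exposure),
                audit$pct_missing_exposure)),
    row("  % success at linkage", sprintf("%.1f", audit$pct_linkage)),
    row("  malformations at birth",
        sprintf("%s (%.1f%%)", fmt_n(audit$n_malformation),
                audit$pct_malformation)),
    row("  missing outcomes",
        sprintf("%s (%.1f%%)", fmt_n(audit$n_missing_outcome),
                audit$pct_missing_outcome)),
    row("N births analysed", fmt_n(audit$n_analysed)),
    row("  % of initial dataset", sprintf("%.1f", audit$pct_of_initial))
  )
  lines
}
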