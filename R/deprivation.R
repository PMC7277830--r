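#' Standardize the five deprivation components
#'
#' z-scores each component percentage (low education, unemployment, home
#' tenancy, lone-parent family, overcrowding) against the pooled reference
#' set of census blocks — all blocks across all cities, unweighted — with
#' the sample standard deviation (denominator n-1). Larger values of every
#' component mean more deprivation (tenancy included: renting counts as
#' deprivation).
#'
#' @param blocks Census-block tibble with the five `pct_*` columns.
#' @return Matrix of z-scores, one row per block, columns named after the
#'   components; attribute `block_id` carries the ids.
#' @export
standardize_components <- function(blocks) {
  comps <- c("pct_low_education", "pct_unemployment", "pct_home_tenancy",
             "pct_lone_parent", "pct_overcrowding")
  stopifnot(all(comps %in% names(blocks)))
  if (nrow(blocks) < 2L)
    stop("standardization needs at least two census blocks", call. = FALSE)
  z <- sapply(comps, function(k) {
    x <- blocks[[k]]
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0)
      stop(sprintf("component `%s` has zero spread across blocks", k),
           call. = FALSE)
    (x - mean(x)) / s
  })
  z <- matrix(z, nrow = nrow(blocks), dimnames = list(NULL, comps))
  attr(z, "block_id") <- blocks$block_id
  z
}

#' Composite deprivation score
#'
#' The unweighted sum of the five standardized components; symmetric in its
#' arguments, larger = more deprived.
#'
#' @param z z-score matrix from [standardize_components()] (or a 5-vector).
#' @return Numeric score per block.
#' @export
deprivation_score <- function(z) {
  if (is.null(dim(z))) return(sum(z))
  rowSums(z)
}

#' Within-city population-weighted deprivation quintiles
#'
#' Orders each city's blocks by ascending deprivation score (ties broken by
#' `block_id`) and walks the cumulative resident population, cutting at 20,
#' 40, 60 and 80% of the city total so each category holds about one fifth
#' of the population; a block straddling a cut goes entirely to the lower
#' quintile. Quintile 1 is the least deprived, 5 the most.
#'
#' @param blocks Census-block tibble (needs `block_id`, `city`,
#'   `resident_population`).
#' @param scores Numeric deprivation score per row of `blocks`.
#' @return Tibble `block_id`, `city`, `score`, `quintile`.
#' @export
assign_quintiles <- function(blocks, scores) {
  stopifnot(nrow(blocks) == length(scores))
  df <- tibble::tibble(block_id = blocks$block_id, city = blocks$city,
                       population = blocks$resident_population,
                       score = scores)
  out <- df |>
    dplyr::group_by(.data$city) |>
    dplyr::group_modify(function(d, key) {
      tot <- sum(d$population)
      if (tot <= 0)
        stop(sprintf("city '%s' has zero total resident population",
                     key$city[[1]]), call. = FALSE)
      o <- order(d$score, d$block_id)
      d <- d[o, , drop = FALSE]
      cum_before <- cumsum(d$population) - d$population
      cuts <- tot * (1:4) / 5
      d$quintile <- 1L + findInterval(cum_before, cuts)
      d
    }) |>
    dplyr::ungroup()
  out[, c("block_id", "city", "score", "quintile")]
}

#' Score and categorize census blocks in one call
#'
#' @param blocks Census-block tibble.
#' @return Tibble `block_id`, `city`, `score`, `quintile`.
#' @export
deprivation_index <- function(blocks) {
  z <- standardize_components(blocks)
  assign_quintiles(blocks, deprivation_score(z))
}
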