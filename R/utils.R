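#' Round half away from zero
#'
#' Decimal rounding with ties going up (`0.05 -> 0.1`), the convention used
#' by the registry tables this package reproduces. Base [round()] rounds
#' half to even, which disagrees on exact ties.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 1).
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_up(c(98.45, 98.4499), 1)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  # tiny eps guards against binary representation of decimal ties
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Stable hash of a configuration object
#'
#' Polynomial rolling hash over the canonical JSON serialisation; used in
#' run manifests so a re-run with the same configuration is recognisable.
#'
#' @param x Any jsonlite-serialisable object.
#' @return Hex string.
#' @export
config_hash <- function(x) {
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE)
  bytes <- utf8ToInt(as.character(json))
  h <- 0
  for (b in bytes) h <- (h * 257 + b) %% 2147483629
  sprintf("%08x", h)
}

# Half-open interval [start, end) day count, Date arithmetic
.days_in <- function(start, end) as.integer(end - start)

# season of a month number: Dec-Feb winter, Mar-May spring, Jun-Aug summer,
# Sep-Nov autumn
.season_of_month <- function(m) {
  c("winter", "winter", "spring", "spring", "spring", "summer",
    "summer", "summer", "autumn", "autumn", "autumn", "winter")[m]
}

.assert_config <- function(ok, field, msg) {
  if (!ok) stop(sprintf("invalid configuration: `%s` %s", field, msg), call. = FALSE)
}
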