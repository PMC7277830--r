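#' Reference birthweight-for-gestational-age table
#'
#' A synthetic reference chart stratified by infant sex, completed
#' gestational week (24-42) and parity class (first, second, higher),
#' emulating the shape of national neonatal anthropometric references: median
#' birthweight rises from roughly 700 g at 24 weeks to about 3.4 kg at 40
#' weeks, boys run ~3% heavier than girls, and parous mothers deliver
#' slightly heavier infants. Each stratum carries the mean and standard
#' deviation of a normal birthweight distribution together with its implied
#' 10th, 50th and 90th percentiles, so the table both drives the generator's
#' birthweight draws and serves as the classifier's reference.
#'
#' @return A tibble with columns `infant_sex`, `gestational_week`,
#'   `parity_class`, `mean_g`, `sd_g`, `p10`, `p50`, `p90`.
#' @export
#' @examples
#' tab <- reference_growth_table()
#' subset(tab, gestational_week == 40 & infant_sex == "boy")
reference_growth_table <- function() {
  anchor_weeks <- c(24, 28, 32, 34, 36, 38, 40, 42)
  anchor_mean  <- c(700, 1150, 1850, 2250, 2750, 3150, 3400, 3550)
  weeks <- 24:42
  base_mean <- stats::approx(anchor_weeks, anchor_mean, xout = weeks)$y
  sex_mult    <- c(boy = 1.03, girl = 0.97)
  parity_mult <- c(first = 0.97, second = 1.01, higher = 1.02)
  grid <- expand.grid(infant_sex = names(sex_mult),
                      gestational_week = weeks,
                      parity_class = names(parity_mult),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  m <- base_mean[match(grid$gestational_week, weeks)] *
    sex_mult[grid$infant_sex] * parity_mult[grid$parity_class]
  s <- pmax(0.13 * m, 90)
  tibble::tibble(
    infant_sex = grid$infant_sex,
    gestational_week = as.integer(grid$gestational_week),
    parity_class = grid$parity_class,
    mean_g = unname(m),
    sd_g = unname(s),
    p10 = unname(stats::qnorm(0.10, m, s)),
    p50 = unname(m),
    p90 = unname(stats::qnorm(0.90, m, s))
  )
}
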