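Package: cohortair
Title: Birth-Cohort Air-Pollution Exposure and Socioeconomic Pipeline
Version: 0.2.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to assemble population-based birth cohorts from
    administrative registries and assess residential air-pollution exposure
    during pregnancy. Provides a synthetic-registry generator (delivery
    certificates, residence histories, census blocks, address-level modelled
    concentrations, daily background-monitor series, hospital discharges),
    record linkage with a sequential selection cascade and per-city audit,
    a composite census-block deprivation index with within-city
    population-weighted quintiles, residence-time-weighted exposure from
    land-use-regression surfaces with temporal back-extrapolation by daily
    monitor ratios over pregnancy windows, pregnancy-outcome derivation
    (preterm birth, term low birthweight, weight for gestational age, Apgar
    class, hypertensive-complication flags), and descriptive outputs
    including high-exposure prevalence crosstabs by socioeconomic indicators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    dplyr,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
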