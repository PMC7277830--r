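#!/usr/bin/env Rscript
# Stage 3 — census-block deprivation index.
#
# Standardizes the five component percentages over the pooled block set,
# sums them into the composite score and assigns within-city
# population-weighted quintiles (1 = least deprived, 5 = most deprived),
# then links each analysed birth to the quintile of the mother's residence
# at delivery.

suppressPackageStartupMessages(library(cohortair))

bundle <- read_bundle(file.path("results", "registry"))
cohort <- utils::read.csv(file.path("results", "analysed_cohort.csv"),
                          stringsAsFactors = FALSE)
cohort[cohort == ""] <- NA
for (dc in c("delivery_date", "lmp_date")) cohort[[dc]] <- as.Date(cohort[[dc]])
cohort <- tibble::as_tibble(cohort)

idx <- deprivation_index(bundle$blocks)
utils::write.csv(idx, file.path("results", "deprivation_index.csv"),
                 row.names = FALSE)

# quintile population shares per city (each should sit near 20%)
shares <- merge(idx, bundle$blocks[, c("block_id", "resident_population")])
share_tab <- do.call(rbind, lapply(split(shares, shares$city), function(d)
  data.frame(city = d$city[1], quintile = 1:5,
             pop_share = as.numeric(tapply(
               d$resident_population, factor(d$quintile, 1:5), sum,
               default = 0) / sum(d$resident_population)))))
message("quintile population shares by city:")
print(round(stats::xtabs(pop_share ~ city + quintile, share_tab), 3))

cohort <- link_deprivation(cohort, bundle$episodes, idx)
utils::write.csv(cohort, file.path("results", "analysed_cohort.csv"),
                 row.names = FALSE, na = "")
message(sprintf("linked deprivation quintiles for %d of %d births",
                sum(!is.na(cohort$deprivation_quintile)), nrow(cohort)))
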