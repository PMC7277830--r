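#!/usr/bin/env Rscript
# Stage 5 — pregnancy outcomes.
#
# Derives preterm birth (<37 completed weeks), term low birthweight
# (<2500 g among term births), weight for gestational age against the
# reference chart (<P10 small, >P90 large), the Apgar class, and the
# hypertensive-complication flags from hospital discharges (ICD-9 642
# family) admitted during pregnancy.

suppressPackageStartupMessages(library(cohortair))

bundle <- read_bundle(file.path("results", "registry"))
cohort <- utils::read.csv(file.path("results", "analysed_cohort.csv"),
                          stringsAsFactors = FALSE)
cohort[cohort == ""] <- NA
for (dc in c("delivery_date", "lmp_date")) cohort[[dc]] <- as.Date(cohort[[dc]])
cohort <- tibble::as_tibble(cohort)

outc <- derive_outcomes(cohort, bundle$hospital, bundle$growth_table)
utils::write.csv(outc, file.path("results", "outcomes.csv"),
                 row.names = FALSE, na = "")

smry <- summarize_outcomes(cohort, outc)
utils::write.csv(smry$continuous, file.path("results",
                                            "outcomes_continuous.csv"),
                 row.names = FALSE)
utils::write.csv(smry$categorical, file.path("results",
                                             "outcomes_categorical.csv"),
                 row.names = FALSE)

tot <- smry$categorical[smry$categorical$city == "Total", ]
line <- function(var, val) {
  r <- tot[tot$variable == var & tot$value == val, ]
  sprintf("%s = %s: %d (%0.1f%%, CI %0.1f-%0.1f)", var, val, r$n, r$pct,
          r$ci_low, r$ci_high)
}
message("pooled outcome prevalences:")
message("  ", line("preterm", "TRUE"))
message("  ", line("term_low_birthweight", "TRUE"))
message("  ", line("weight_for_ga", "small"))
message("  ", line("weight_for_ga", "large"))
message("  ", line("apgar_class", "normal"))
cc <- smry$continuous[smry$continuous$city == "Total", ]
message(sprintf("  gestational age %.1f (%.1f) wk, birthweight %.0f (%.0f) g",
                cc$gestational_weeks_mean, cc$gestational_weeks_sd,
                cc$birthweight_mean, cc$birthweight_sd))
hyp <- merge(outc, cohort[, "mother_id", drop = FALSE])
message(sprintf("  hypertensive disorders: any 642 %d, preeclampsia/eclampsia %d",
                sum(hyp$hypertension), sum(hyp$any_preeclampsia_eclampsia)))
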