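#!/usr/bin/env Rscript
# Per-exercise-minute group comparisons: Kruskal-Wallis omnibus with Nemenyi
# post hoc at each minute, per outcome and sex, under subject attrition.
# Summarizes at which minutes the constitutional types separate and writes the
# machine-readable twin of the time-course figures.

library(thermoex)
library(dplyr)

report <- run_pipeline("results/study")
cmp <- report$comparisons

dir.create("results", showWarnings = FALSE)
readr::write_csv(cmp, "results/per_minute_comparisons.csv")

sig <- cmp |>
  filter(tested, p < 0.05) |>
  group_by(sex, outcome) |>
  summarise(n_sig_minutes = dplyr::n(),
            minutes = paste(minute, collapse = ","),
            .groups = "drop")
readr::write_csv(sig, "results/significant_minutes.csv")

cat("minutes with a significant omnibus difference, by outcome and sex:\n")
print(as.data.frame(sig))

lsr <- cmp |> filter(outcome == "lsr_chest", sex == "male", tested)
cat("\nchest LSR, males: letters per minute (a TE-SE, b TE-SY, c SE-SY):\n")
print(as.data.frame(lsr[, c("minute", "n_te", "n_se", "n_sy", "H", "p",
                            "letters")]), digits = 3)
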