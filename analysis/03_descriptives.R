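#!/usr/bin/env Rscript
# Step 3: stratified descriptive characterization of the selected cases —
# demographics, outcomes, regions, indications, time to onset, annual trend.

suppressPackageStartupMessages(library(pvsignal))

db <- read_icsr_database("results/synthetic_db", "csv")
sel <- select_cases(db)
cases <- filter_cases(sel$db, sel$assignments$case_id)

summ <- summarize_cases(cases, sel$assignments)
readr::write_csv(descriptives_wide(summ), "results/descriptives_wide.csv",
                 na = "")
readr::write_csv(summ$scalars, "results/descriptives_scalars.csv", na = "")
tt <- tto_summary(sel$assignments)
readr::write_csv(tt, "results/tto_summary.csv", na = "")
ac <- annual_counts(cases, c(2011, 2024))
readr::write_csv(ac, "results/annual_counts.csv")

dir.create("scratch", showWarnings = FALSE)
ggplot2::ggsave("scratch/annual_counts.png", plot_annual_counts(ac),
                width = 7, height = 4, dpi = 150)

early <- early_onset_fraction(sel$assignments)
serious <- serious_fraction(cases)
cat(sprintf("%d selected cases; %.1f%% serious; median onset %s days (n=%d); %.1f%% within 90 days\n",
            n_cases(cases), serious$pct,
            format(tt$median[tt$stratum == "Total"]),
            tt$n[tt$stratum == "Total"], as.numeric(early)))
cat("combo vs nivolumab monotherapy onset medians:",
    tt$median[tt$stratum == "ipilimumab_nivolumab"], "vs",
    tt$median[tt$stratum == "nivolumab"], "days\n")
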