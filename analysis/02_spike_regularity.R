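#!/usr/bin/env Rscript
# Step 2: per-unit discharge statistics. Reads the spike/epoch tables from
# step 1, computes mean ISI, CV, CV* and the regular/irregular label plus the
# 10-s resting rate for every unit, tabulates the cohort census, and runs the
# normal-vs-PD resting-rate contrast within each (organ x regularity)
# stratum.

suppressPackageStartupMessages(library(vnstim))

data_dir <- "results/01_data"
out <- "results/02_spikes"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

trains <- read_spike_tables(data_dir)
metrics <- do.call(rbind, lapply(trains, spike_train_metrics))
write_delim_table(metrics, file.path(out, "unit_metrics.tsv"))

census <- summarize_cohort(metrics)
write_delim_table(census$by_condition, file.path(out, "census_by_condition.tsv"))
write_delim_table(census$by_regularity, file.path(out, "census_by_regularity.tsv"))

fr <- population_fr_contrast(metrics)
write_delim_table(fr, file.path(out, "fr_contrasts.tsv"))

cat(sprintf("units analyzed: %d (threshold CV* = %.2f)\n", census$n_total,
            default_regularity_threshold()))
bc <- census$by_condition
for (org in c("canal", "otolith")) {
  n_norm <- bc$n[bc$organ == org & bc$condition == "normal"]
  pct <- bc$pct[bc$organ == org & bc$condition == "normal"]
  cat(sprintf("  %s: %d/%d (%.1f%%) from non-lesioned animals\n", org, n_norm,
              sum(bc$n[bc$organ == org]), pct))
}
cat("normal-vs-PD resting-rate contrasts (per stratum):\n")
print(fr[, c("organ", "regularity", "mean_a", "mean_b", "t_stat", "p_value")],
      row.names = FALSE, digits = 3)
cat("wrote", out, "\n")
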