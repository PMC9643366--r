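#!/usr/bin/env Rscript
# Step 5: glutamate-receptor group statistics. Left/right control contrast,
# the PD-vs-control increase, and the dose-response of receptor density
# against delivered GVS charge, per receptor subtype.

suppressPackageStartupMessages(library(vnstim))

data_dir <- "results/01_data"
out <- "results/05_receptors"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

tab <- read_delim_table(file.path(data_dir, "receptor_counts.tsv"))
charges <- read_delim_table("results/04_charge/charge_table.tsv")

sides <- rbind(side_contrast(tab, "AMPA"), side_contrast(tab, "NMDA"))
write_delim_table(sides, file.path(out, "side_contrasts.tsv"))
cat(sprintf("left/right contrasts: min p = %.3f (no side difference expected)\n",
            min(sides$p_value)))

pdc <- rbind(pd_vs_control(tab, "AMPA"), pd_vs_control(tab, "NMDA"))
write_delim_table(pdc, file.path(out, "pd_vs_control.tsv"))
for (i in seq_len(nrow(pdc))) {
  cat(sprintf("%s control -> PD: %.2f -> %.2f counts/mm2 (t = %.2f, p = %.2g)\n",
              pdc$receptor[i], pdc$mean_a[i], pdc$mean_b[i], pdc$t_stat[i],
              pdc$p_value[i]))
}

for (rec in c("AMPA", "NMDA")) {
  dr <- dose_response(tab, rec, charges = charges)
  write_delim_table(dr$summary, file.path(out, sprintf("dose_response_%s.tsv", rec)))
  if (!is.null(dr$comparisons)) {
    write_delim_table(dr$comparisons,
                      file.path(out, sprintf("dose_comparisons_%s.tsv", rec)))
  }
  cat(sprintf("%s dose-response (mean +- SEM by charge):\n", rec))
  print(transform(dr$summary, mean = round(mean, 2), sem = round(sem, 2)),
        row.names = FALSE)
  cat(sprintf("  monotone non-increasing with charge: %s\n",
              dr$monotone_decreasing))
}
cat("wrote", out, "\n")
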