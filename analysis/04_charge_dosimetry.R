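#!/usr/bin/env Rscript
# Step 4: electrical-charge dosimetry. The total charge delivered by the GVS
# schedule (20 stimuli of 3 s per set, one per 60 s, 3 sets) at each group's
# amplitude, by charge conservation q = n_sets * sum of per-pulse integrals.

suppressPackageStartupMessages(library(vnstim))

out <- "results/04_charge"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

charges <- charge_per_group()
write_delim_table(charges, file.path(out, "charge_table.tsv"))

cat("delivered charge per treatment group:\n")
print(transform(charges, charge_C = signif(charge_C, 6)), row.names = FALSE)
cat("wrote", out, "\n")
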