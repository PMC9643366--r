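#!/usr/bin/env Rscript
# Step 1: simulate the study's raw material — 65 vestibular-nucleus spike
# trains (32 canal / 33 otolith, normal and 6-OHDA PD), the five-group
# AMPA/NMDA receptor-count tables, and the rota-rod durations — and write
# them as delimited text under results/01_data/.

suppressPackageStartupMessages(library(vnstim))

seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1L
out <- "results/01_data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- default_run_config(seed = seed)
trains <- generate_cohort(cfg)
write_spike_tables(trains, out)

specs <- default_receptor_specs()
rec <- generate_receptor_table(specs, seed = seed + 1L,
                               field_area_mm2 = cfg$receptors$field_area_mm2)
write_delim_table(rec, file.path(out, "receptor_counts.tsv"))

rr <- generate_rotarod(seed = seed + 2L)
write_delim_table(rr, file.path(out, "rotarod.tsv"))

jsonlite::write_json(list(seed = seed, n_units = length(trains),
                          n_receptor_rows = nrow(rec)),
                     file.path(out, "generation_manifest.json"),
                     auto_unbox = TRUE, digits = NA)

cat(sprintf("simulated %d units (%d canal, %d otolith)\n", length(trains),
            sum(vapply(trains, `[[`, character(1), "organ") == "canal"),
            sum(vapply(trains, `[[`, character(1), "organ") == "otolith")))
cat(sprintf("receptor table: %d field counts across %d groups x 2 receptors\n",
            nrow(rec), length(unique(rec$group))))
cat(sprintf("rota-rod (n = %d): pre-training %.1f s, trained %.1f s, post-PD %.1f s (means)\n",
            nrow(rr), mean(rr$pre_training_s), mean(rr$trained_s),
            mean(rr$post_pd_s)))
cat("wrote", out, "\n")
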