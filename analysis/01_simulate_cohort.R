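#!/usr/bin/env Rscript
# Simulate the study cohort: 216 high-risk patients sampled between weeks
# 10 and 29, ~12% BV, ~20% spontaneous preterm among known deliveries,
# with one synthetic GC-IMS spectrum per swab (preterm-linked amplitude
# effect on 10 analyte peaks). Writes the cohort tables and two example
# spectrum files; full spectra are regenerated from the seed by later
# scripts rather than stored.

suppressPackageStartupMessages(library(vocptb))

seed <- 20170118L
out <- "results"
dir.create(out, showWarnings = FALSE)

params <- cohort_sim_params(seed = seed)
co <- generate_cohort(params)

message(sprintf("simulated %d patients, %d swabs",
                nrow(co$patients), nrow(co$swabs)))
s <- summarize_cohort(co$patients, co$swabs)
for (nm in setdiff(names(s), "delivery_categories")) {
  message(sprintf("  %-28s %3d / %3d  (%.1f%%)", nm,
                  s[[nm]]$count, s[[nm]]$n, s[[nm]]$pct))
}

pts <- co$patients
pts$delivery_gestation <- format_gestation(pts$delivery_days)
write.csv(pts, file.path(out, "patients.csv"), row.names = FALSE)
sw <- co$swabs
sw$gestation <- format_gestation(sw$gestation_days)
write.csv(sw, file.path(out, "swabs.csv"), row.names = FALSE)

# two small example files in the text dialect (one per class): a cropped,
# thresholded excerpt keeps the illustration while staying diff-friendly
set_pre <- build_analysis_set(co$patients, co$swabs, "preterm", "first")
pick <- c(set_pre$sample_id[set_pre$label == 1][1],
          set_pre$sample_id[set_pre$label == 0][1])
excerpt <- crop_window(80, 160, 20, 80)
for (id in pick) {
  sp <- apply_threshold(crop_spectrum(co$spectra[[id]], excerpt), 5)
  write_spectrum(sp, file.path(out, paste0("example_", id, ".txt")))
}
message("wrote patients.csv, swabs.csv and example spectrum excerpts under results/")
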