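#!/usr/bin/env Rscript
# Odor activity of the volatile fraction: monomer/dimer bookkeeping, chemical
# classes, and ROAV screening of the GC-IMS peak table.

suppressPackageStartupMessages(library(flavoromics))
dir.create("results", showWarnings = FALSE)

fx <- load_fixtures()

compounds <- deduplicate_forms(fx$voc_table)
cat(sprintf("%d peak entries -> %d compounds after monomer/dimer merging\n",
            nrow(fx$voc_table) / 5, length(compounds)))

full <- analyte_table(rbind(
  as.data.frame(fx$voc_table)[, c("analyte_id", "form", "sample_group",
                                  "replicate", "value", "sd")],
  as.data.frame(fx$voc_others)[, c("analyte_id", "form", "sample_group",
                                   "replicate", "value", "sd")]),
  "relative_percent")
classes <- aggregate_classes(full, fx$voc_class_map)
utils::write.csv(classes, "results/02_class_totals.csv", row.names = FALSE)
cat("Chemical-class relative contents (%), sample A:\n")
print(classes[classes$sample_group == "A", c("class", "total", "n_compounds")],
      row.names = FALSE)

roav <- compute_roav(fx$voc_table, fx$voc_thresholds)
write_score_table(roav$scores, "results/02_roav_scores.csv")
cat("Reference odorant per sample (ROAV = 100):\n")
print(roav$reference[, c("sample_group", "analyte_id", "form")],
      row.names = FALSE)
cat(sprintf("%d compounds lack a published odor threshold and are excluded: %s\n",
            length(roav$excluded), paste(roav$excluded, collapse = ", ")))

s <- screen_roav(roav, merge_forms = TRUE)
cat(sprintf("Key odorants (merged ROAV >= 1, %d):\n  %s\n", length(s$key),
            paste(s$key, collapse = ", ")))
cat(sprintf("Odor modifiers (0.1 <= ROAV < 1, %d):\n  %s\n", length(s$modifier),
            paste(s$modifier, collapse = ", ")))
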