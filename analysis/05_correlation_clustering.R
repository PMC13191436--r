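#!/usr/bin/env Rscript
# Taste-odor correlation panel and sample clustering on the published group
# means: key amino acids and nucleotides against the VIP-selected volatiles.

suppressPackageStartupMessages(library(flavoromics))
dir.create("results", showWarnings = FALSE)
seed <- 1

fx <- load_fixtures()
groups <- sort(unique(fx$faa_table$sample_group))

wide <- function(table, ids = NULL) {
  df <- as.data.frame(table)
  lab <- paste0(df$analyte_id,
                c(none = "", monomer = "-M", dimer = "-D")[df$form])
  if (is.null(ids)) ids <- unique(lab)
  sapply(ids, function(v) {
    d <- df[lab == v, ]
    d$value[match(groups, d$sample_group)]
  })
}

# VIP-selected volatiles from the simulated-replicate OPLS-DA (stage 04)
key <- screen_roav(compute_roav(fx$voc_table, fx$voc_thresholds))$key
keep <- canonical_id(fx$voc_table$analyte_id) %in% canonical_id(key)
means <- analyte_table(as.data.frame(fx$voc_table)[keep, , drop = FALSE],
                       "relative_percent")
m <- fit_oplsda(analyte_matrix(simulate_replicates(simulation_config(
  means, n_replicates = 3, seed = seed, renormalize = FALSE))), seed = seed)
vip_vars <- names(sort(m$vip[m$vip > 1], decreasing = TRUE))

tav_key <- screen_tav(tav_table(fx$faa_table, fx$faa_thresholds))$key
taste <- cbind(wide(fx$faa_table, tav_key), wide(fx$nucleotide_table))
odor <- wide(fx$voc_table, vip_vars)

panel <- pearson_matrix(taste, odor)
utils::write.csv(as.data.frame(panel), "results/05_correlation_panel.csv",
                 row.names = FALSE)
sig <- panel[panel$flag != "ns", ]
cat(sprintf("correlation panel: %d taste x %d odor variables over %d samples\n",
            ncol(taste), ncol(odor), nrow(taste)))
cat(sprintf("%d pairs significant at p < 0.05:\n", nrow(sig)))
print(sig[order(sig$p), ], row.names = FALSE)

# sample clustering on z-scored volatile profiles (all 50 peaks)
M <- wide(fx$voc_table)
rownames(M) <- groups
h <- hierarchical_cluster(t(zscore_rows(t(M))), "euclidean", "average")
cat("sample dendrogram:", as_newick(h), "\n")
writeLines(as_newick(h), "results/05_sample_clusters.nwk")
utils::write.csv(data.frame(position = seq_along(h$order),
                            sample = h$labels[h$order]),
                 "results/05_sample_order.csv", row.names = FALSE)
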