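#!/usr/bin/env Rscript
# Multivariate discrimination of the cooking times: PCA, OPLS-DA with VIP,
# and a 200-permutation validation, on the simulated replicate-level table of
# ROAV-selected key compounds (the published replicate data are unreleased,
# so these statistics characterize the simulated stand-in, not the study).

suppressPackageStartupMessages(library(flavoromics))
dir.create("results", showWarnings = FALSE)
seed <- 1

fx <- load_fixtures()
key <- screen_roav(compute_roav(fx$voc_table, fx$voc_thresholds))$key
keep <- canonical_id(fx$voc_table$analyte_id) %in% canonical_id(key)
means <- analyte_table(as.data.frame(fx$voc_table)[keep, , drop = FALSE],
                       "relative_percent")
dm <- analyte_matrix(simulate_replicates(simulation_config(
  means, n_replicates = 3, seed = seed, renormalize = FALSE)))

pc <- pca(dm, n_components = 4, scaling = "unit_variance")
cat(sprintf("PCA: PC1 %.1f%%, PC2 %.1f%% (cumulative %.1f%%)\n",
            100 * pc$explained_variance_fraction[1],
            100 * pc$explained_variance_fraction[2],
            100 * sum(pc$explained_variance_fraction[1:2])))
utils::write.csv(data.frame(sample = rownames(dm$X), group = dm$groups,
                            pc$scores),
                 "results/04_pca_scores.csv", row.names = FALSE)

m <- fit_oplsda(dm, n_orthogonal = 1, cv_folds = 7, seed = seed)
print(m)
utils::write.csv(data.frame(variable = names(m$vip), vip = unname(m$vip)),
                 "results/04_vip.csv", row.names = FALSE)
sel <- sort(m$vip[m$vip > 1], decreasing = TRUE)
cat(sprintf("%d variables with VIP > 1:\n", length(sel)))
print(round(sel, 3))
merged <- unique(split_form(names(sel))$analyte_id)
cat(sprintf("=> %d compounds after monomer/dimer merging: %s\n",
            length(merged), paste(merged, collapse = ", ")))

perm <- permutation_test(dm, n_permutations = 200, seed = seed)
print(perm)
utils::write.csv(data.frame(correlation = perm$correlation,
                            R2Y = perm$R2Y_perm, Q2 = perm$Q2_perm),
                 "results/04_permutations.csv", row.names = FALSE)
cat(sprintf("original Q2 beats the permuted 95th percentile: %s\n",
            perm$Q2 > stats::quantile(perm$Q2_perm, 0.95)))
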