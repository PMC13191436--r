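# Small synthetic worlds shared across tests.

# write lines to a temp file and return its path
textConnection_file <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}

# flat 17-analyte x 5-group mean table (no discrimination)
flat_means <- function(n_analytes = 17, mean = 5, sd = 0.5,
                       groups = LETTERS[1:5]) {
  d <- expand.grid(analyte_id = paste0("v", seq_len(n_analytes)),
                   sample_group = groups, KEEP.OUT.ATTRS = FALSE,
                   stringsAsFactors = FALSE)
  d$value <- mean
  d$sd <- sd
  analyte_table(d, "concentration_mg_per_kg")
}

# biomarker-style recovery world: variable j elevated by `shift` SD in group j
# only, so exactly length(ids) variables discriminate with independent
# between-group directions
biomarker_means <- function(n_analytes = 17, n_marker = 5, shift = 5,
                            mean = 5, sd = 0.5) {
  tab <- as.data.frame(flat_means(n_analytes, mean, sd))
  for (j in seq_len(n_marker)) {
    hit <- tab$analyte_id == paste0("v", j) & tab$sample_group == LETTERS[j]
    tab$value[hit] <- tab$value[hit] + shift * sd
  }
  analyte_table(tab, "concentration_mg_per_kg")
}

sim_matrix <- function(means, seed, n_replicates = 3) {
  analyte_matrix(simulate_replicates(simulation_config(
    means, n_replicates = n_replicates, seed = seed, renormalize = FALSE)))
}

# fixture VOC group means restricted to the merged key odorants, the stand-in
# replicate-level world for the multivariate stage
fixture_key_means <- function(fx = load_fixtures()) {
  key <- screen_roav(compute_roav(fx$voc_table, fx$voc_thresholds))$key
  keep <- canonical_id(fx$voc_table$analyte_id) %in% canonical_id(key)
  analyte_table(as.data.frame(fx$voc_table)[keep, , drop = FALSE],
                "relative_percent")
}

# wide group-mean matrix (groups x analytes) from a fixture analyte table
group_mean_matrix <- function(table, ids = NULL) {
  df <- as.data.frame(table)
  lab <- paste0(df$analyte_id,
                c(none = "", monomer = "-M", dimer = "-D")[df$form])
  if (!is.null(ids)) df <- df[lab %in% ids, , drop = FALSE]
  lab <- paste0(df$analyte_id,
                c(none = "", monomer = "-M", dimer = "-D")[df$form])
  groups <- sort(unique(df$sample_group))
  cols <- unique(lab)
  M <- matrix(NA_real_, length(groups), length(cols),
              dimnames = list(groups, cols))
  M[cbind(match(df$sample_group, groups), match(lab, cols))] <- df$value
  M
}
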