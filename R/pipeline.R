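# End-to-end orchestration: fixtures in -> TAV/ROAV score tables, screened
# compound lists, OPLS-DA + VIP + permutation report, correlation panel out.

#' Write an analyte table as CSV
#'
#' @param table an [analyte_table()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_analyte_table <- function(table, path) {
  stopifnot(inherits(table, "analyte_table"))
  df <- as.data.frame(table)
  df$value_kind <- value_kind(table)
  utils::write.csv(df, path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end run. All cut-offs default to the
#' conventional values: activity cut 1 (a compound above its threshold
#' contributes), modifier cut 0.1, VIP cut 1.
#'
#' @param out_dir output directory (created if absent).
#' @param seed master seed; every stochastic stage derives from it.
#' @param tav_key_cut,tav_mod_cut TAV classification cut-offs.
#' @param roav_key_cut,roav_mod_cut ROAV classification cut-offs.
#' @param vip_cut VIP selection cut-off for the correlation panel.
#' @param merge_forms merge monomer/dimer forms when screening odorants.
#' @param n_replicates simulated replicates per group for the multivariate
#'   stage (the study's replicate-level data are unpublished).
#' @param scaling,cv_folds,n_orthogonal,n_permutations multivariate
#'   settings, see [fit_oplsda()] and [permutation_test()].
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1,
                            tav_key_cut = 1, tav_mod_cut = 0.1,
                            roav_key_cut = 1, roav_mod_cut = 0.1,
                            vip_cut = 1, merge_forms = TRUE,
                            n_replicates = 3, scaling = "unit_variance",
                            cv_folds = 7, n_orthogonal = 1,
                            n_permutations = 200) {
  cuts <- c(tav_key_cut, tav_mod_cut, roav_key_cut, roav_mod_cut, vip_cut)
  if (any(cuts <= 0))
    stop("pipeline_config: cut-offs must be positive", call. = FALSE)
  if (tav_mod_cut >= tav_key_cut || roav_mod_cut >= roav_key_cut)
    stop("pipeline_config: modifier cut must be below key cut", call. = FALSE)
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 tav_key_cut = tav_key_cut, tav_mod_cut = tav_mod_cut,
                 roav_key_cut = roav_key_cut, roav_mod_cut = roav_mod_cut,
                 vip_cut = vip_cut, merge_forms = isTRUE(merge_forms),
                 n_replicates = n_replicates, scaling = scaling,
                 cv_folds = cv_folds, n_orthogonal = n_orthogonal,
                 n_permutations = n_permutations),
            class = "pipeline_config")
}

#' Run the full flavoromics pipeline
#'
#' Executes, on the packaged fixtures plus seeded synthetic replicates:
#' (1) TAV scoring and key/modifier screening of the free amino acids, with
#' taste-class totals; (2) ROAV scoring and key-odorant screening of the
#' volatile table; (3) OPLS-DA with VIP and label-permutation validation,
#' fitted on simulated replicate-level data restricted to the ROAV-selected
#' key compounds (the manifest marks this provenance: simulated replicates
#' around published means, not a reproduction of unpublished raw data);
#' (4) a Pearson correlation panel of the VIP-selected volatiles against the
#' key amino acids and the nucleotides on the published group means; and
#' (5) a JSON manifest with the seed, every cut value, exclusions and stage
#' status. Any stage failure leaves the completed outputs in place, writes a
#' `FAILED` marker into the manifest and signals an error.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  manifest <- list(
    package_version = as.character(utils::packageVersion("flavoromics")),
    seed = config$seed,
    cuts = config[c("tav_key_cut", "tav_mod_cut", "roav_key_cut",
                    "roav_mod_cut", "vip_cut")],
    merge_forms = config$merge_forms,
    multivariate = config[c("n_replicates", "scaling", "cv_folds",
                            "n_orthogonal", "n_permutations")],
    data_provenance = paste("fixtures-means for scoring and correlations;",
                            "simulated replicates (truncated Gaussian around",
                            "fixture means/SDs) for OPLS-DA"),
    stages = list(), exclusions = list())
  finish <- function(status) {
    manifest$status <<- status
    jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE, digits = NA, null = "null")
  }
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) e)
    if (inherits(res, "error")) {
      manifest$stages[[name]] <<- paste("FAILED:", conditionMessage(res))
      finish("FAILED")
      stop("pipeline stage '", name, "' failed: ", conditionMessage(res),
           call. = FALSE)
    }
    manifest$stages[[name]] <<- "ok"
    res
  }

  fx <- load_fixtures()

  tav <- stage("taste_scoring", {
    sc <- tav_table(fx$faa_table, fx$faa_thresholds,
                    key_cut = config$tav_key_cut, mod_cut = config$tav_mod_cut)
    write_score_table(sc, out("tav_scores.csv"))
    totals <- aggregate_taste_classes(fx$faa_table, fx$faa_thresholds)
    utils::write.csv(totals, out("taste_class_totals.csv"), row.names = FALSE)
    sc
  })
  tav_screen <- screen_tav(tav)
  manifest$key_taste_compounds <- tav_screen$key
  manifest$modifier_taste_compounds <- tav_screen$modifier
  manifest$exclusions$taste <- unique(
    tav$analyte_id[tav$classification == "excluded_no_threshold"])

  roav <- stage("odor_scoring", {
    r <- compute_roav(fx$voc_table, fx$voc_thresholds,
                      key_cut = config$roav_key_cut,
                      mod_cut = config$roav_mod_cut)
    write_score_table(r$scores, out("roav_scores.csv"))
    r
  })
  odor_screen <- screen_roav(roav, merge_forms = config$merge_forms,
                             key_cut = config$roav_key_cut,
                             mod_cut = config$roav_mod_cut)
  manifest$key_odor_compounds <- odor_screen$key
  manifest$modifier_odor_compounds <- odor_screen$modifier
  manifest$exclusions$odor <- roav$excluded

  model <- stage("multivariate", {
    key_canon <- canonical_id(odor_screen$key)
    keep <- canonical_id(split_form(fx$voc_table$analyte_id)$analyte_id) %in%
      key_canon | canonical_id(fx$voc_table$analyte_id) %in% key_canon
    if (!any(keep))
      stop("no variables left after ROAV screening (key cut ",
           config$roav_key_cut, ")")
    means <- analyte_table(as.data.frame(fx$voc_table)[keep, , drop = FALSE],
                           "relative_percent")
    sim <- simulate_replicates(simulation_config(
      means, n_replicates = config$n_replicates, seed = config$seed,
      renormalize = FALSE))
    write_analyte_table(sim, out("simulated_replicates.csv"))
    dm <- analyte_matrix(sim)
    m <- fit_oplsda(dm, n_orthogonal = config$n_orthogonal,
                    cv_folds = config$cv_folds, scaling = config$scaling,
                    seed = config$seed)
    jsonlite::write_json(list(R2X = m$R2X, R2Y = m$R2Y, Q2 = m$Q2,
                              n_predictive = m$n_predictive,
                              n_orthogonal = m$n_orthogonal),
                         out("oplsda_summary.json"), auto_unbox = TRUE,
                         digits = NA)
    utils::write.csv(data.frame(variable = names(m$vip), vip = unname(m$vip)),
                     out("vip.csv"), row.names = FALSE)
    perm <- permutation_test(dm, n_permutations = config$n_permutations,
                             seed = config$seed,
                             n_orthogonal = config$n_orthogonal,
                             cv_folds = config$cv_folds,
                             scaling = config$scaling)
    jsonlite::write_json(list(n_permutations = perm$n_permutations,
                              Q2 = perm$Q2, R2Y = perm$R2Y,
                              Q2_perm_median = stats::median(perm$Q2_perm),
                              Q2_perm_q95 = unname(stats::quantile(perm$Q2_perm, 0.95)),
                              intercepts = as.list(perm$intercepts)),
                         out("permutation_summary.json"), auto_unbox = TRUE,
                         digits = NA)
    m
  })

  stage("correlation", {
    vips <- sort(model$vip[model$vip > config$vip_cut], decreasing = TRUE)
    if (length(vips) == 0) stop("no variables exceed the VIP cut")
    groups <- sort(unique(fx$faa_table$sample_group))
    taste_ids <- c(tav_screen$key, unique(fx$nucleotide_table$analyte_id))
    taste_mat <- sapply(taste_ids, function(id) {
      src <- rbind(as.data.frame(fx$faa_table)[, c("analyte_id", "sample_group", "value")],
                   as.data.frame(fx$nucleotide_table)[, c("analyte_id", "sample_group", "value")])
      d <- src[src$analyte_id == id, ]
      d$value[match(groups, d$sample_group)]
    })
    voc_lab <- paste0(fx$voc_table$analyte_id,
                      c(none = "", monomer = "-M", dimer = "-D")[fx$voc_table$form])
    odor_mat <- sapply(names(vips), function(v) {
      d <- fx$voc_table[voc_lab == v, ]
      d$value[match(groups, d$sample_group)]
    })
    panel <- pearson_matrix(taste_mat, odor_mat)
    utils::write.csv(as.data.frame(panel), out("correlation_panel.csv"),
                     row.names = FALSE)
    panel
  })

  finish("ok")
  invisible(manifest)
}

#' Write a simulated dataset ready for the pipeline
#'
#' @param config a [simulation_config()].
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
simulate_dataset <- function(config, dir) {
  stopifnot(inherits(config, "simulation_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, "simulated_replicates.csv")
  write_analyte_table(simulate_replicates(config), paths)
  if (!is.null(config$enose_profile)) {
    p2 <- file.path(dir, "simulated_enose.csv")
    write_analyte_table(simulate_enose(config), p2)
    paths <- c(paths, p2)
  }
  invisible(paths)
}
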