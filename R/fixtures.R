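#' Load the packaged study tables
#'
#' The package ships the published group-mean tables of a cooking-time study
#' of *Sarcodon imbricatus* soup (five cooking times, 30--150 min, labelled
#' A--E) as plain CSV fixtures:
#'
#' * `faa_table` -- 17 free amino acids, concentrations in mg/kg (mean and
#'   printed SD per group);
#' * `faa_thresholds` -- taste thresholds in mg/kg with umami/sweet/bitter/
#'   aromatic class tags. Cys and Tyr have no published threshold; Arg's
#'   threshold (500 mg/kg) is reconstructed from its printed content/TAV
#'   ratio and flagged `reconstructed`;
#' * `nucleotide_table` -- five 5'-nucleotides (GMP, AMP, UMP, CMP, IMP) in
#'   mg/kg. No taste thresholds are published for them;
#' * `voc_table` -- 50 GC-IMS volatile peak entries (37 compounds plus 13
#'   proton-bound dimer duplicates) as relative contents in percent;
#' * `voc_others` -- the unidentified residual fraction per sample, carried
#'   as an explicit pseudo-analyte so per-sample totals close to 100%;
#' * `voc_thresholds` -- odor thresholds in water (mg/kg) and descriptors;
#'   compounds without a published threshold are retained with `NA`;
#' * `voc_class_map` -- compound to chemical class
#'   (aldehyde/ketone/alcohol/ester/ether/olefin/heterocyclic).
#'
#' @return a list of class `study_fixtures`.
#' @examples
#' fx <- load_fixtures()
#' nrow(fx$faa_table)   # 17 amino acids x 5 groups
#' @export
load_fixtures <- function() {
  p <- function(f) system.file("extdata", f, package = "flavoromics", mustWork = TRUE)
  fx <- list(
    faa_table = read_analyte_table(p("faa_content.csv"), "concentration_mg_per_kg"),
    faa_thresholds = read_threshold_db(p("faa_thresholds.csv"), "taste"),
    nucleotide_table = read_analyte_table(p("nucleotide_content.csv"),
                                          "concentration_mg_per_kg"),
    voc_table = read_analyte_table(p("voc_content.csv"), "relative_percent"),
    voc_others = read_analyte_table(p("voc_others.csv"), "relative_percent"),
    voc_thresholds = read_threshold_db(p("voc_odor_thresholds.csv"), "odor"),
    voc_class_map = utils::read.csv(p("voc_class_map.csv"),
                                    stringsAsFactors = FALSE))
  class(fx) <- "study_fixtures"
  fx
}

#' @export
print.study_fixtures <- function(x, ...) {
  cat("<study_fixtures>\n",
      sprintf("  faa_table: %d rows | nucleotide_table: %d rows | voc_table: %d rows\n",
              nrow(x$faa_table), nrow(x$nucleotide_table), nrow(x$voc_table)),
      sprintf("  thresholds: %d taste, %d odor | class map: %d compounds\n",
              nrow(x$faa_thresholds), nrow(x$voc_thresholds),
              nrow(x$voc_class_map)))
  invisible(x)
}
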