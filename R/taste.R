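#' Taste activity value
#'
#' TAV = concentration / taste threshold (both mg/kg, so the score is
#' dimensionless). TAV > 1 marks a compound whose concentration exceeds its
#' recognition threshold and therefore contributes actively to taste;
#' 0.1--1 marks a taste modifier.
#'
#' @param concentration non-negative concentration(s), mg/kg.
#' @param threshold positive taste threshold(s), mg/kg; `NA` yields `NA`
#'   (compound excluded for lack of a threshold, not an error).
#' @return numeric TAV, same length as the inputs.
#' @examples
#' compute_tav(242.34, 80)    # 3.029
#' @export
compute_tav <- function(concentration, threshold) {
  if (any(!is.na(threshold) & threshold <= 0))
    stop("compute_tav: threshold must be positive", call. = FALSE)
  if (any(!is.na(concentration) & concentration < 0))
    stop("compute_tav: concentration must be non-negative", call. = FALSE)
  concentration / threshold
}

.group_mean_scores <- function(scores) {
  # mean score per (analyte, group) -- identity for group-mean tables,
  # averages replicates otherwise
  agg <- stats::aggregate(score ~ analyte_id + sample_group, data = scores,
                          FUN = mean, na.action = NULL)
  agg
}

.classify_by_group <- function(scores, key_cut, mod_cut, key_rule) {
  # key_rule "all": score above key_cut in every group (taste convention);
  # key_rule "any": in at least one group (odor convention).
  gm <- .group_mean_scores(scores)
  out <- lapply(split(gm, canonical_id(gm$analyte_id)), function(d) {
    s <- d$score
    if (all(is.na(s))) return("excluded_no_threshold")
    if (key_rule == "all" && all(s > key_cut)) return("key")
    if (key_rule == "any" && any(s >= key_cut)) return("key")
    if (any(s >= mod_cut)) return("modifier")
    "negligible"
  })
  unlist(out)
}

#' TAV score table for an analyte table
#'
#' Computes one TAV per row of the content table and classifies each analyte:
#' `key` if its TAV exceeds `key_cut` in *every* sample group, `modifier` if
#' it reaches `mod_cut` in at least one group without being key, `negligible`
#' otherwise, and `excluded_no_threshold` when the database has no threshold.
#' The all-groups rule for `key` reproduces published practice, where an
#' amino acid crossing 1 in a single group is still listed among modifiers.
#'
#' @param table an [analyte_table()] of concentrations (mg/kg).
#' @param db a taste [threshold_db()].
#' @param key_cut,mod_cut classification cut-offs (defaults 1 and 0.1).
#' @return a [score_table()] with `score_kind = "TAV"`.
#' @export
tav_table <- function(table, db, key_cut = 1, mod_cut = 0.1) {
  stopifnot(inherits(table, "analyte_table"))
  if (value_kind(table) != "concentration_mg_per_kg")
    stop("tav_table expects a concentration table (mg/kg)", call. = FALSE)
  thr <- lookup_threshold(db, table$analyte_id)
  sc <- data.frame(analyte_id = table$analyte_id, form = table$form,
                   sample_group = table$sample_group,
                   score = compute_tav(table$value, thr),
                   stringsAsFactors = FALSE)
  cls <- .classify_by_group(sc, key_cut, mod_cut, key_rule = "all")
  sc$classification <- cls[canonical_id(sc$analyte_id)]
  score_table(sc, "TAV")
}

#' Key/modifier screening of a score table
#'
#' @param scores a [score_table()].
#' @return list with character vectors `key` and `modifier` (analyte ids in
#'   order of first appearance).
#' @export
screen_tav <- function(scores) {
  stopifnot(inherits(scores, "score_table"))
  first <- scores[!duplicated(canonical_id(scores$analyte_id)), ]
  list(key = first$analyte_id[first$classification == "key"],
       modifier = first$analyte_id[first$classification == "modifier"])
}

#' Aggregate concentrations by taste class
#'
#' Sums concentrations per taste class (umami/sweet/bitter/aromatic) and
#' sample group. An analyte may belong to several classes (Arg is both sweet
#' and bitter) and then contributes to each; unclassified analytes count
#' only toward the grand total, which always covers every analyte once.
#'
#' @param table an [analyte_table()] of concentrations (mg/kg).
#' @param db a taste [threshold_db()] whose `taste_class` column holds
#'   semicolon-separated class memberships.
#' @return data.frame with columns `taste_class`, `sample_group`, `total`;
#'   the grand total appears as class `"total"`.
#' @export
aggregate_taste_classes <- function(table, db) {
  stopifnot(inherits(table, "analyte_table"), inherits(db, "threshold_db"))
  cls_raw <- db$taste_class[match(canonical_id(table$analyte_id),
                                  canonical_id(db$analyte_id))]
  rows <- list()
  for (i in seq_len(nrow(table))) {
    classes <- if (is.na(cls_raw[i]) || cls_raw[i] == "") character(0) else
      strsplit(cls_raw[i], ";", fixed = TRUE)[[1]]
    for (cl in trimws(classes))
      rows[[length(rows) + 1]] <- data.frame(
        taste_class = cl, sample_group = table$sample_group[i],
        value = table$value[i], stringsAsFactors = FALSE)
    rows[[length(rows) + 1]] <- data.frame(
      taste_class = "total", sample_group = table$sample_group[i],
      value = table$value[i], stringsAsFactors = FALSE)
  }
  long <- do.call(rbind, rows)
  out <- stats::aggregate(value ~ taste_class + sample_group, data = long, FUN = sum)
  names(out)[names(out) == "value"] <- "total"
  out[order(out$taste_class, out$sample_group), , drop = FALSE]
}
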