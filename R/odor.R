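# Relative odor activity value (ROAV) scoring.
#
# The compound with the largest (relative content / odor threshold) ratio in
# a sample anchors the scale at ROAV = 100; every other compound is scored
# relative to it:
#   ROAV_i = (C%_i / C%_ref) * (T_ref / T_i) * 100.

.roav_sample_frames <- function(table) {
  split(seq_len(nrow(table)), .sample_key(table))
}

#' Select the ROAV reference compound of one sample
#'
#' Returns the (analyte, form) maximizing relative content over odor
#' threshold; compounds without a threshold are skipped. Ties are broken by
#' lexicographic analyte id (then form) so selection is deterministic.
#'
#' @param table an [analyte_table()] of relative contents restricted to one
#'   sample (one group, one replicate).
#' @param db an odor [threshold_db()].
#' @return one-row data.frame: `analyte_id`, `form`, `value`, `threshold`.
#' @export
select_reference <- function(table, db) {
  stopifnot(inherits(table, "analyte_table"))
  if (length(unique(.sample_key(table))) != 1)
    stop("select_reference expects a single-sample table", call. = FALSE)
  thr <- lookup_threshold(db, table$analyte_id)
  ok <- !is.na(thr)
  if (!any(ok))
    stop("select_reference: no analyte has a known odor threshold", call. = FALSE)
  ratio <- table$value[ok] / thr[ok]
  cand <- data.frame(analyte_id = table$analyte_id[ok], form = table$form[ok],
                     value = table$value[ok], threshold = thr[ok],
                     ratio = ratio, stringsAsFactors = FALSE)
  cand <- cand[order(-cand$ratio, canonical_id(cand$analyte_id), cand$form), ]
  cand[1, c("analyte_id", "form", "value", "threshold")]
}

#' Compute ROAV scores
#'
#' Scores every (analyte, form, sample) of a normalized volatile table
#' against the sample's reference compound. With `reference = "auto"` the
#' reference is the per-sample argmax of content/threshold (so the maximum
#' ROAV in each sample is exactly 100); a fixed reference id (e.g.
#' `"1-Octanal-M"`) may be supplied instead. Compounds without a threshold
#' are scored `NA` and classified `excluded_no_threshold`.
#'
#' @param table an [analyte_table()] of relative contents (percent).
#' @param db an odor [threshold_db()].
#' @param reference `"auto"` or an analyte name (with optional `-M`/`-D`
#'   form suffix) to pin as reference in every sample.
#' @param key_cut,mod_cut screening cut-offs passed to the classification
#'   (defaults 1 and 0.1; a compound is key if any form reaches `key_cut`
#'   in any sample).
#' @return object of class `roav_result`: list with `scores` (a
#'   [score_table()]), `reference` (per-sample reference rows) and
#'   `excluded` (analytes lacking thresholds).
#' @export
compute_roav <- function(table, db, reference = "auto", key_cut = 1,
                         mod_cut = 0.1) {
  stopifnot(inherits(table, "analyte_table"))
  if (value_kind(table) != "relative_percent")
    stop("compute_roav expects a relative-content table", call. = FALSE)
  thr <- lookup_threshold(db, table$analyte_id)
  score <- rep(NA_real_, nrow(table))
  refs <- list()
  for (idx in .roav_sample_frames(table)) {
    sub <- analyte_table(as.data.frame(table)[idx, , drop = FALSE],
                         value_kind(table))
    if (identical(reference, "auto")) {
      ref <- select_reference(sub, db)
    } else {
      sf <- split_form(reference)
      hit <- canonical_id(sub$analyte_id) == canonical_id(sf$analyte_id) &
        (sf$form == "none" | sub$form == sf$form)
      if (!any(hit))
        stop("compute_roav: fixed reference '", reference,
             "' not present in sample", call. = FALSE)
      i <- which(hit)[1]
      ref <- data.frame(analyte_id = sub$analyte_id[i], form = sub$form[i],
                        value = sub$value[i],
                        threshold = lookup_threshold(db, sub$analyte_id[i]),
                        stringsAsFactors = FALSE)
      if (is.na(ref$threshold))
        stop("compute_roav: fixed reference has no odor threshold", call. = FALSE)
    }
    if (ref$value <= 0)
      stop("compute_roav: reference compound has zero relative content in sample ",
           sub$sample_group[1], call. = FALSE)
    refs[[length(refs) + 1]] <- cbind(
      sample_group = sub$sample_group[1], replicate = sub$replicate[1], ref,
      stringsAsFactors = FALSE)
    score[idx] <- (table$value[idx] / ref$value) * (ref$threshold / thr[idx]) * 100
  }
  sc <- data.frame(analyte_id = table$analyte_id, form = table$form,
                   sample_group = table$sample_group,
                   replicate = table$replicate, score = score,
                   stringsAsFactors = FALSE)
  cls <- .classify_by_group(sc, key_cut, mod_cut, key_rule = "any")
  sc$classification <- cls[canonical_id(sc$analyte_id)]
  out <- list(scores = score_table(sc, "ROAV"),
              reference = do.call(rbind, refs),
              excluded = unique(table$analyte_id[is.na(thr)]))
  class(out) <- "roav_result"
  out
}

#' @export
print.roav_result <- function(x, ...) {
  cat(sprintf("<roav_result> %d scores, %d samples, %d analytes excluded (no threshold)\n",
              nrow(x$scores), nrow(x$reference), length(x$excluded)))
  cat("references:", paste(unique(paste0(x$reference$analyte_id,
      c(none = "", monomer = "-M", dimer = "-D")[x$reference$form])),
      collapse = ", "), "\n")
  invisible(x)
}

#' Screen ROAV scores into key and modifier odorants
#'
#' With `merge_forms = TRUE` (the compound-counting convention) the monomer
#' and dimer of one compound are one candidate: it is key when *any* form in
#' *any* sample reaches `key_cut`, a modifier when its maximum merged score
#' lies in `[mod_cut, key_cut)`. With `merge_forms = FALSE` each (analyte,
#' form) peak is screened separately.
#'
#' @param result a `roav_result` from [compute_roav()].
#' @param merge_forms merge monomer/dimer forms by compound name (default
#'   `TRUE`).
#' @param key_cut,mod_cut cut-offs (defaults 1 and 0.1; `key_cut` is
#'   inclusive).
#' @return list with character vectors `key` and `modifier`.
#' @export
screen_roav <- function(result, merge_forms = TRUE, key_cut = 1, mod_cut = 0.1) {
  stopifnot(inherits(result, "roav_result"))
  sc <- result$scores
  label <- if (merge_forms) sc$analyte_id else
    paste0(sc$analyte_id, c(none = "", monomer = "-M", dimer = "-D")[sc$form])
  keep <- !is.na(sc$score)
  mx <- tapply(sc$score[keep], canonical_id(label[keep]), max)
  disp <- label[keep][!duplicated(canonical_id(label[keep]))]
  names(disp) <- canonical_id(disp)
  ord <- names(mx)[order(names(mx))]
  list(key = unname(disp[ord[mx[ord] >= key_cut]]),
       modifier = unname(disp[ord[mx[ord] >= mod_cut & mx[ord] < key_cut]]))
}
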