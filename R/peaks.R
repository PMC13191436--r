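# Semi-quantification bookkeeping for volatile peak tables: normalization to
# relative content, monomer/dimer deduplication, chemical-class aggregation.

.sample_key <- function(table) paste(table$sample_group, table$replicate, sep = "\r")

#' Normalize a peak table to relative content
#'
#' Semi-quantification by the normalization method: within each sample
#' (group, and replicate when present) every value is divided by the sample
#' total and multiplied by 100, so per-sample values sum to exactly 100%.
#'
#' @param raw an [analyte_table()] of intensities or concentrations.
#' @return an [analyte_table()] with `value_kind = "relative_percent"`; any
#'   `sd` column is scaled by the same per-sample factor.
#' @examples
#' t <- analyte_table(data.frame(analyte_id = c("x", "y", "z"),
#'   sample_group = "A", value = c(2, 3, 5)), "concentration_mg_per_kg")
#' normalize_to_relative_content(t)$value   # 20 30 50
#' @export
normalize_to_relative_content <- function(raw) {
  stopifnot(inherits(raw, "analyte_table"))
  key <- .sample_key(raw)
  totals <- tapply(raw$value, key, sum)
  zero <- names(totals)[totals <= 0]
  if (length(zero) > 0)
    stop("normalization error: all-zero sample(s): ",
         paste(sub("\r.*$", "", zero), collapse = ", "), call. = FALSE)
  fac <- 100 / as.numeric(totals[key])
  out <- as.data.frame(raw)
  out$value <- raw$value * fac
  out$sd <- raw$sd * fac
  analyte_table(out, "relative_percent")
}

#' Deduplicate monomer/dimer forms
#'
#' GC-IMS reports the proton-bound dimer of a compound as a second peak of
#' the same analyte; for compound counting the two forms are one compound.
#'
#' @param table an [analyte_table()] with form labels.
#' @return character vector of unique analyte ids, in order of first
#'   appearance.
#' @export
deduplicate_forms <- function(table) {
  stopifnot(inherits(table, "analyte_table"))
  table$analyte_id[!duplicated(canonical_id(table$analyte_id))]
}

#' Aggregate relative contents by chemical class
#'
#' @param table a normalized [analyte_table()] (`relative_percent`).
#' @param classes data.frame mapping `analyte` (or `analyte_id`) to `class`;
#'   analytes absent from the map fall into class `"other"`.
#' @return data.frame with columns `class`, `sample_group`, `replicate`,
#'   `total` and `n_compounds` (unique compounds per class).
#' @export
aggregate_classes <- function(table, classes) {
  stopifnot(inherits(table, "analyte_table"))
  if (value_kind(table) != "relative_percent")
    stop("aggregate_classes expects a normalized relative-content table",
         call. = FALSE)
  a_col <- if (!is.null(classes$analyte_id)) "analyte_id" else "analyte"
  cl <- classes$class[match(canonical_id(table$analyte_id),
                            canonical_id(classes[[a_col]]))]
  cl[is.na(cl)] <- "other"
  d <- data.frame(class = cl, sample_group = table$sample_group,
                  replicate = table$replicate, value = table$value,
                  analyte_id = table$analyte_id, stringsAsFactors = FALSE)
  d$replicate[is.na(d$replicate)] <- 0L
  out <- stats::aggregate(value ~ class + sample_group + replicate, data = d,
                          FUN = sum)
  names(out)[names(out) == "value"] <- "total"
  counts <- vapply(split(d$analyte_id, d$class),
                   function(a) length(unique(canonical_id(a))), integer(1))
  out$n_compounds <- as.integer(counts[out$class])
  out$replicate[out$replicate == 0L] <- NA_integer_
  out[order(out$sample_group, out$replicate, out$class), , drop = FALSE]
}
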