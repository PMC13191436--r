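# Readers/writers for the delimited text formats the pipeline touches.
# Delimiter is auto-detected among comma / tab / semicolon; decimal point only.

.detect_sep <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0)
    stop("format error: empty file: ", path, call. = FALSE)
  counts <- vapply(c(",", "\t", ";"), function(s)
    lengths(regmatches(first, gregexpr(s, first, fixed = TRUE))), integer(1))
  if (all(counts == 0))
    stop("format error: no delimiter (comma/tab/semicolon) found in header of ",
         path, call. = FALSE)
  c(",", "\t", ";")[which.max(counts)]
}

.pick_col <- function(df, candidates) {
  hit <- match(candidates, tolower(names(df)))
  hit <- hit[!is.na(hit)]
  if (length(hit) == 0) NULL else names(df)[hit[1]]
}

#' Read a delimited analyte content table
#'
#' Expects a header naming an analyte column, a sample-group column and a
#' value column; `form`, `replicate` and `sd` columns are optional. When no
#' `form` column is present, trailing `-M`/`-D` name suffixes are split into
#' the monomer/dimer form.
#'
#' @param path file path to a CSV/TSV/semicolon-delimited table.
#' @param value_kind `"concentration_mg_per_kg"` or `"relative_percent"`.
#' @return an [analyte_table()].
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("analyte,group,value", "1-Nonanal-D,A,2.28"), f)
#' read_analyte_table(f, "relative_percent")
#' @export
read_analyte_table <- function(path, value_kind) {
  sep <- .detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "")
  a_col <- .pick_col(df, c("analyte_id", "analyte", "compound", "compound_name", "name"))
  g_col <- .pick_col(df, c("sample_group", "group", "sample"))
  v_col <- .pick_col(df, c("value", "content", "relative_content", "concentration"))
  need <- c(analyte = is.null(a_col), group = is.null(g_col), value = is.null(v_col))
  if (any(need))
    stop("format error: missing required column(s): ",
         paste(names(need)[need], collapse = ", "), " in ", path, call. = FALSE)
  f_col <- .pick_col(df, "form")
  out <- data.frame(analyte_id = as.character(df[[a_col]]),
                    sample_group = as.character(df[[g_col]]),
                    value = as.numeric(df[[v_col]]),
                    stringsAsFactors = FALSE)
  if (!is.null(f_col)) {
    out$form <- as.character(df[[f_col]])
  } else {
    sf <- split_form(out$analyte_id)
    out$analyte_id <- sf$analyte_id
    out$form <- sf$form
  }
  r_col <- .pick_col(df, "replicate")
  if (!is.null(r_col)) out$replicate <- as.integer(df[[r_col]])
  s_col <- .pick_col(df, "sd")
  if (!is.null(s_col)) out$sd <- as.numeric(df[[s_col]])
  extra <- setdiff(names(df), c(a_col, g_col, v_col, f_col, r_col, s_col))
  for (e in extra) out[[e]] <- df[[e]]
  analyte_table(out, value_kind)
}

#' Read a taste or odor threshold database
#'
#' A dash (`-` or en/em dash) or empty threshold cell parses as a missing
#' threshold; the record is retained and flagged rather than dropped.
#' `-M`/`-D` form suffixes are stripped (thresholds belong to the compound);
#' per-form rows carrying the same threshold are collapsed, conflicting ones
#' are an error.
#'
#' @param path file path.
#' @param modality `"taste"` or `"odor"`.
#' @return a [threshold_db()].
#' @export
read_threshold_db <- function(path, modality = c("taste", "odor")) {
  modality <- match.arg(modality)
  sep <- .detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "", na.strings = c("NA", ""))
  a_col <- .pick_col(df, c("analyte_id", "analyte", "compound", "compound_name", "name"))
  t_col <- .pick_col(df, c("threshold", "taste_threshold", "odor_threshold"))
  if (is.null(a_col) || is.null(t_col))
    stop("format error: threshold table needs analyte and threshold columns in ",
         path, call. = FALSE)
  raw <- as.character(df[[t_col]])
  missing_mark <- is.na(raw) | grepl("^\\s*(-|–|—)?\\s*$", raw)
  thr <- suppressWarnings(as.numeric(gsub(",", "", raw)))
  if (any(!missing_mark & is.na(thr)))
    stop("format error: unparseable threshold value(s): ",
         paste(unique(raw[!missing_mark & is.na(thr)]), collapse = ", "),
         call. = FALSE)
  thr[missing_mark] <- NA_real_
  sf <- split_form(as.character(df[[a_col]]))
  out <- data.frame(analyte_id = sf$analyte_id, threshold = thr,
                    stringsAsFactors = FALSE)
  d_col <- .pick_col(df, c("descriptor", "odor_characteristics", "odor"))
  if (!is.null(d_col)) out$descriptor <- as.character(df[[d_col]])
  c_col <- .pick_col(df, c("taste_class", "class"))
  if (!is.null(c_col)) out$taste_class <- as.character(df[[c_col]])
  r_col <- .pick_col(df, "reconstructed")
  if (!is.null(r_col)) out$reconstructed <- as.logical(df[[r_col]])
  # collapse duplicate per-form rows of one compound
  key <- canonical_id(out$analyte_id)
  if (anyDuplicated(key) > 0) {
    for (k in unique(key[duplicated(key)])) {
      thr_k <- unique(out$threshold[key == k])
      if (length(thr_k[!is.na(thr_k)]) > 1)
        stop("threshold db validation error: conflicting thresholds for ",
             out$analyte_id[key == k][1], call. = FALSE)
    }
    out <- out[!duplicated(key), , drop = FALSE]
  }
  threshold_db(out, modality)
}

#' Write a score table as delimited text
#'
#' Columns are emitted in a stable order; missing scores (compounds with no
#' threshold) are written as the literal `NA`. [read_score_table()] restores
#' an identical object.
#'
#' @param table a [score_table()].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_score_table <- function(table, path) {
  stopifnot(inherits(table, "score_table"))
  cols <- c("analyte_id", "form", "sample_group", "score", "classification")
  df <- as.data.frame(table)[, cols, drop = FALSE]
  df$score_kind <- rep(attr(table, "score_kind"), nrow(df))
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = TRUE, na = "NA")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop("I/O error writing score table to ", path, ": ",
         conditionMessage(ok), call. = FALSE)
  invisible(path)
}

#' @rdname write_score_table
#' @export
read_score_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  kind <- if (nrow(df) > 0) df$score_kind[1] else "TAV"
  df$score_kind <- NULL
  score_table(df, kind)
}
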