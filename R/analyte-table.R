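#' Canonicalize an analyte name
#'
#' Matching between content tables and threshold databases is done on a
#' canonical form of the compound name: case-insensitive, with internal
#' whitespace collapsed. Stereochemistry prefixes such as `(E)-` / `(Z)-`
#' are preserved (they distinguish real isomers).
#'
#' @param x character vector of analyte names.
#' @return character vector of canonical ids.
#' @export
canonical_id <- function(x) {
  tolower(gsub("\\s+", " ", trimws(x)))
}

#' Split monomer/dimer form suffixes from analyte names
#'
#' GC-IMS peak tables report proton-bound dimers of a compound as separate
#' rows, marked by a trailing `-M` (monomer) or `-D` (dimer), any case.
#' That suffix is the only recognised form marker.
#'
#' @param x character vector of names, possibly carrying `-M`/`-D` suffixes.
#' @return data.frame with columns `analyte_id` (suffix stripped) and `form`
#'   (`"monomer"`, `"dimer"` or `"none"`).
#' @export
split_form <- function(x) {
  suffix <- toupper(sub("^.*-([MDmd])$", "\\1", x))
  has <- grepl("-[MDmd]$", x)
  form <- ifelse(!has, "none", ifelse(suffix == "M", "monomer", "dimer"))
  data.frame(analyte_id = ifelse(has, sub("-[MDmd]$", "", x), x),
             form = form, stringsAsFactors = FALSE)
}

.value_kinds <- c("concentration_mg_per_kg", "relative_percent")
.forms <- c("monomer", "dimer", "none")

#' Construct an analyte table
#'
#' The central long-format container of the pipeline: one measured value per
#' (analyte, form, sample group, replicate). Values are concentrations in
#' mg/kg or relative contents in percent; a whole table carries exactly one
#' of the two kinds. Group-mean tables may carry the printed standard
#' deviation in `sd`.
#'
#' @param df data.frame with columns `analyte_id`, `sample_group`, `value`
#'   and optionally `form`, `replicate`, `sd` (extra columns are kept).
#' @param value_kind `"concentration_mg_per_kg"` or `"relative_percent"`.
#' @return validated object of class `analyte_table` (a data.frame).
#' @export
analyte_table <- function(df, value_kind) {
  value_kind <- match.arg(value_kind, .value_kinds)
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (is.null(df$form)) df$form <- "none"
  if (is.null(df$replicate)) df$replicate <- NA_integer_
  if (is.null(df$sd)) df$sd <- NA_real_
  lead <- c("analyte_id", "form", "sample_group", "replicate", "value", "sd")
  df <- df[, c(lead, setdiff(names(df), lead)), drop = FALSE]
  df$sample_group <- as.character(df$sample_group)
  df$replicate <- as.integer(df$replicate)
  attr(df, "value_kind") <- value_kind
  class(df) <- c("analyte_table", "data.frame")
  validate_analyte_table(df)
}

#' @export
#' @rdname analyte_table
#' @param x an `analyte_table`.
validate_analyte_table <- function(x) {
  stopifnot(inherits(x, "analyte_table"))
  req <- c("analyte_id", "form", "sample_group", "replicate", "value", "sd")
  missing_col <- setdiff(req, names(x))
  if (length(missing_col) > 0)
    stop("analyte table format error: missing column(s) ",
         paste(missing_col, collapse = ", "), call. = FALSE)
  if (!all(x$form %in% .forms))
    stop("analyte table: form must be one of ", paste(.forms, collapse = "/"),
         call. = FALSE)
  bad <- which(!is.finite(x$value) | x$value < 0)
  if (length(bad) > 0)
    stop("analyte table validation error: negative or non-finite value in row(s) ",
         paste(utils::head(bad, 5), collapse = ", "),
         " (", paste(utils::head(x$analyte_id[bad], 5), collapse = ", "), ")",
         call. = FALSE)
  if (any(!is.na(x$sd) & x$sd < 0))
    stop("analyte table validation error: negative sd", call. = FALSE)
  key <- paste(canonical_id(x$analyte_id), x$form, x$sample_group, x$replicate,
               sep = "\r")
  if (anyDuplicated(key) > 0)
    stop("analyte table validation error: duplicate (analyte, form, group, replicate): ",
         x$analyte_id[anyDuplicated(key)], call. = FALSE)
  if (is.null(value_kind(x)) || !value_kind(x) %in% .value_kinds)
    stop("analyte table: invalid value_kind", call. = FALSE)
  x
}

#' Value kind of an analyte table
#' @param x an `analyte_table`.
#' @return the `value_kind` attribute.
#' @export
value_kind <- function(x) attr(x, "value_kind", exact = TRUE)

#' @export
print.analyte_table <- function(x, ...) {
  cat(sprintf("<analyte_table> %d rows, %d analytes, %d groups [%s]\n",
              nrow(x), length(unique(canonical_id(x$analyte_id))),
              length(unique(x$sample_group)), value_kind(x)))
  print(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

#' Construct a threshold database
#'
#' One taste or odor threshold (mg/kg) per analyte. Missing thresholds
#' (printed as a dash in the source tables) are kept with `threshold = NA`
#' so downstream scoring can report exclusions explicitly instead of
#' silently dropping compounds.
#'
#' @param df data.frame with columns `analyte_id`, `threshold` and
#'   optionally `descriptor`, `taste_class` (semicolon-separated multi
#'   membership) and `reconstructed` (logical provenance flag).
#' @param modality `"taste"` or `"odor"`.
#' @return object of class `threshold_db`.
#' @export
threshold_db <- function(df, modality = c("taste", "odor")) {
  modality <- match.arg(modality)
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (is.null(df$analyte_id) || is.null(df$threshold))
    stop("threshold db format error: need analyte_id and threshold columns",
         call. = FALSE)
  if (is.null(df$descriptor)) df$descriptor <- NA_character_
  if (is.null(df$taste_class)) df$taste_class <- NA_character_
  if (is.null(df$reconstructed)) df$reconstructed <- FALSE
  df$threshold <- as.numeric(df$threshold)
  bad <- which(!is.na(df$threshold) & df$threshold <= 0)
  if (length(bad) > 0)
    stop("threshold db validation error: non-positive threshold for ",
         paste(df$analyte_id[bad], collapse = ", "), call. = FALSE)
  if (anyDuplicated(canonical_id(df$analyte_id)) > 0)
    stop("threshold db validation error: duplicate analyte ",
         df$analyte_id[anyDuplicated(canonical_id(df$analyte_id))], call. = FALSE)
  attr(df, "modality") <- modality
  class(df) <- c("threshold_db", "data.frame")
  df
}

#' Look up thresholds for a set of analytes
#'
#' @param db a `threshold_db`.
#' @param ids analyte names (form suffixes allowed; they are stripped before
#'   matching since thresholds are per compound, not per ion form).
#' @return numeric vector of thresholds, `NA` where unknown.
#' @export
lookup_threshold <- function(db, ids) {
  stopifnot(inherits(db, "threshold_db"))
  stems <- split_form(ids)$analyte_id
  db$threshold[match(canonical_id(stems), canonical_id(db$analyte_id))]
}

#' Construct a score table
#'
#' Holds TAV or ROAV scores per (analyte, form, sample group) together with
#' the key/modifier classification of each analyte.
#'
#' @param df data.frame with columns `analyte_id`, `form`, `sample_group`,
#'   `score`, `classification`.
#' @param score_kind `"TAV"` or `"ROAV"`.
#' @return object of class `score_table`.
#' @export
score_table <- function(df, score_kind = c("TAV", "ROAV")) {
  score_kind <- match.arg(score_kind)
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  req <- c("analyte_id", "form", "sample_group", "score", "classification")
  if (!all(req %in% names(df)))
    stop("score table format error: missing column(s) ",
         paste(setdiff(req, names(df)), collapse = ", "), call. = FALSE)
  ok_class <- c("key", "modifier", "negligible", "excluded_no_threshold")
  if (!all(df$classification %in% ok_class))
    stop("score table: invalid classification", call. = FALSE)
  if (any(!is.na(df$score) & df$score < 0))
    stop("score table: negative score", call. = FALSE)
  if (any(is.na(df$score) != (df$classification == "excluded_no_threshold")))
    stop("score table: NA score must coincide with excluded_no_threshold",
         call. = FALSE)
  attr(df, "score_kind") <- score_kind
  class(df) <- c("score_table", "data.frame")
  df
}
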