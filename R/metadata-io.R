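# Readers for the two scan-configuration files: the variable-information file
# (one row per biobank field: its declared field type, data code and per-scan
# flags) and the data-coding file (one row per data code: ordinal status,
# value ordering, value reassignments, optional default value).
#
# File dialects (tab-separated, header row, literal `NA` = absent):
#
# variable info:  field_id  field_type  data_code  excluded  trait_equivalent
#                 cat_mult_missingness
#   field_type in {CONTINUOUS, INTEGER, CAT_SINGLE, CAT_MULTIPLE};
#   cat_mult_missingness in {OTHER_VALUE_HOLDERS, RESPONDERS, ALL} (categorical
#   multiple fields only).
#
# data coding:    coding_id  is_ordinal  ordering  reassignments  default_value
#   ordering: raw values in rank order joined by `|` (e.g. "3|2|1");
#   reassignments: comma-separated `old=new` pairs, `new` may be `NA` to send a
#   raw value to missing (e.g. "-1=NA,555=0.5").

FIELD_TYPES <- c("CONTINUOUS", "INTEGER", "CAT_SINGLE", "CAT_MULTIPLE")
CAT_MULT_OPTIONS <- c("OTHER_VALUE_HOLDERS", "RESPONDERS", "ALL")
DATA_TYPES <- c("CONTINUOUS", "ORDERED", "UNORDERED", "BINARY")

VARINFO_COLUMNS <- c("field_id", "field_type", "data_code", "excluded",
                     "trait_equivalent", "cat_mult_missingness")
CODING_COLUMNS <- c("coding_id", "is_ordinal", "ordering", "reassignments",
                    "default_value")

#' Load the variable-information file
#'
#' One row per biobank field: its declared field type (continuous, integer,
#' categorical single, categorical multiple), the data code its categorical
#' values follow, whether it is excluded a priori from the scan, whether it is
#' essentially the same phenotype as the trait of interest (tested for
#' validation only), and — for categorical multiple fields — which participants
#' count as `FALSE` in the expanded binary variables.
#'
#' @param path Path to a tab-separated file with columns `field_id`,
#'   `field_type`, `data_code`, `excluded`, `trait_equivalent`,
#'   `cat_mult_missingness`.
#' @return A `data.table` with one validated row per field.
#' @export
load_variable_info <- function(path) {
  vi <- data.table::fread(path, sep = "\t", header = TRUE, na.strings = "NA")
  if ("cat_mult_missingness" %in% names(vi)) {
    vi[, cat_mult_missingness := as.character(cat_mult_missingness)]
  }
  missing_cols <- setdiff(VARINFO_COLUMNS, names(vi))
  phs_assert(length(missing_cols) == 0L, "schema_error",
             sprintf("variable info file missing column(s): %s",
                     paste(missing_cols, collapse = ", ")))
  if (nrow(vi) == 0L) {
    phs_log("variable info %s: 0 rows", path)
    return(vi[, VARINFO_COLUMNS, with = FALSE])
  }
  dup <- vi$field_id[duplicated(vi$field_id)]
  phs_assert(length(dup) == 0L, "duplicate_field",
             sprintf("duplicate field id(s) in variable info: %s",
                     paste(unique(dup), collapse = ", ")))
  bad_type <- setdiff(unique(vi$field_type), FIELD_TYPES)
  phs_assert(length(bad_type) == 0L, "schema_error",
             sprintf("unknown field type(s): %s", paste(bad_type, collapse = ", ")))
  bad_opt <- setdiff(stats::na.omit(unique(vi$cat_mult_missingness)), CAT_MULT_OPTIONS)
  phs_assert(length(bad_opt) == 0L, "schema_error",
             sprintf("unknown cat-multiple missingness option(s): %s",
                     paste(bad_opt, collapse = ", ")))
  vi[, `:=`(field_id = as.integer(field_id),
            excluded = as.logical(excluded),
            trait_equivalent = as.logical(trait_equivalent),
            data_code = suppressWarnings(as.integer(data_code)))]
  no_code <- vi[field_type == "CAT_SINGLE" & is.na(data_code), field_id]
  phs_assert(length(no_code) == 0L, "missing_data_code",
             sprintf("categorical (single) field(s) without a data code: %s",
                     paste(no_code, collapse = ", ")))
  phs_log("variable info %s: %d fields (%d excluded a priori, %d trait-equivalent)",
          path, nrow(vi), sum(vi$excluded), sum(vi$trait_equivalent))
  vi[, VARINFO_COLUMNS, with = FALSE]
}

parse_ordering <- function(s) {
  if (is.na(s) || !nzchar(s)) return(NULL)
  vals <- as.numeric(strsplit(s, "|", fixed = TRUE)[[1]])
  phs_assert(!anyNA(vals), "schema_error",
             sprintf("non-numeric value in ordering '%s'", s))
  phs_assert(!anyDuplicated(vals), "schema_error",
             sprintf("duplicate value in ordering '%s'", s))
  vals
}

parse_reassignments <- function(s) {
  if (is.na(s) || !nzchar(s)) return(NULL)
  pairs <- strsplit(strsplit(s, ",", fixed = TRUE)[[1]], "=", fixed = TRUE)
  bad <- vapply(pairs, length, 1L) != 2L
  phs_assert(!any(bad), "schema_error",
             sprintf("malformed reassignment(s) in '%s'", s))
  old <- as.numeric(vapply(pairs, `[`, "", 1L))
  new_raw <- vapply(pairs, `[`, "", 2L)
  new <- suppressWarnings(as.numeric(new_raw))       # "NA" -> NA = to-missing
  phs_assert(!anyNA(old) && !anyDuplicated(old), "schema_error",
             sprintf("invalid reassignment sources in '%s'", s))
  # no chains: a value that is a reassignment target may not itself be reassigned
  chained <- intersect(new[!is.na(new)], old)
  phs_assert(length(chained) == 0L, "invalid_reassignment",
             sprintf("chained reassignment via value(s) %s in '%s'",
                     paste(chained, collapse = ", "), s))
  list(from = old, to = new)
}

#' Load the data-coding file
#'
#' A data code is a reusable description of a categorical value set shared by
#' one or more fields: whether the categories are ordered (and in which order),
#' raw-value reassignments applied before any other processing (including
#' recoding a value to missing), and an optional default substituted for
#' missing values.
#'
#' @param path Path to a tab-separated file with columns `coding_id`,
#'   `is_ordinal`, `ordering`, `reassignments`, `default_value`.
#' @return A named list of `phs_data_coding` records keyed by coding id.
#' @export
load_data_coding <- function(path) {
  dc <- data.table::fread(path, sep = "\t", header = TRUE, na.strings = "NA",
                          colClasses = list(character = c("ordering", "reassignments")))
  missing_cols <- setdiff(CODING_COLUMNS, names(dc))
  phs_assert(length(missing_cols) == 0L, "schema_error",
             sprintf("data coding file missing column(s): %s",
                     paste(missing_cols, collapse = ", ")))
  dup <- dc$coding_id[duplicated(dc$coding_id)]
  phs_assert(length(dup) == 0L, "duplicate_field",
             sprintf("duplicate coding id(s): %s", paste(unique(dup), collapse = ", ")))
  codings <- lapply(seq_len(nrow(dc)), function(i) {
    row <- dc[i]
    data_coding(coding_id = as.integer(row$coding_id),
                is_ordinal = as.logical(row$is_ordinal),
                ordering = parse_ordering(row$ordering),
                reassignments = parse_reassignments(row$reassignments),
                default_value = if (is.na(row$default_value)) NULL else as.numeric(row$default_value))
  })
  names(codings) <- as.character(dc$coding_id)
  phs_log("data codings %s: %d codes", path, length(codings))
  codings
}

#' Construct a data-coding record
#'
#' @param coding_id Integer id of the data code.
#' @param is_ordinal Do the categories have a meaningful order?
#' @param ordering Optional numeric vector of raw values in rank order.
#' @param reassignments Optional list with numeric vectors `from` and `to`
#'   (`NA` in `to` sends a raw value to missing); no chains allowed.
#' @param default_value Optional value substituted for missing after recoding.
#' @return A `phs_data_coding` object.
#' @export
data_coding <- function(coding_id, is_ordinal, ordering = NULL,
                        reassignments = NULL, default_value = NULL) {
  if (!is.null(ordering)) {
    phs_assert(!anyDuplicated(ordering), "schema_error",
               sprintf("coding %d: duplicate values in ordering", coding_id))
  }
  if (!is.null(reassignments)) {
    chained <- intersect(reassignments$to[!is.na(reassignments$to)], reassignments$from)
    phs_assert(length(chained) == 0L, "invalid_reassignment",
               sprintf("coding %d: chained reassignment", coding_id))
  }
  structure(list(coding_id = coding_id, is_ordinal = isTRUE(is_ordinal),
                 ordering = ordering, reassignments = reassignments,
                 default_value = default_value),
            class = "phs_data_coding")
}

format_ordering <- function(ordering) {
  if (is.null(ordering)) NA_character_ else paste(ordering, collapse = "|")
}

format_reassignments <- function(re) {
  if (is.null(re)) return(NA_character_)
  to <- ifelse(is.na(re$to), "NA", as.character(re$to))
  paste(paste0(re$from, "=", to), collapse = ",")
}

#' Serialize metadata back to their file dialects
#'
#' Inverse of [load_variable_info()] / [load_data_coding()]; loading then
#' re-writing is lossless for every field the schema defines.
#'
#' @param vi A variable-information `data.table`.
#' @param codings A list of `phs_data_coding` records.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_variable_info <- function(vi, path) {
  data.table::fwrite(vi, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' @rdname write_variable_info
#' @export
write_data_coding <- function(codings, path) {
  dc <- data.table::rbindlist(lapply(codings, function(cd) {
    data.table::data.table(
      coding_id = cd$coding_id,
      is_ordinal = cd$is_ordinal,
      ordering = format_ordering(cd$ordering),
      reassignments = format_reassignments(cd$reassignments),
      default_value = if (is.null(cd$default_value)) NA_real_ else cd$default_value)
  }))
  data.table::fwrite(dc, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}
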