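# Value recoding driven by the data-coding file. Order of operations:
# declared reassignments first, then (categorical fields only) remaining
# negative values become missing — biobank codings consistently use negative
# values for 'prefer not to answer' / 'do not know' — and finally the coding's
# default value fills remaining missing entries when one is declared.

#' Recode raw field values under a data coding
#'
#' @param values Numeric vector of raw values.
#' @param coding A `phs_data_coding`, or `NULL` for no coding.
#' @param field_type The field's declared type; negative values are sent to
#'   missing only for categorical field types (negative measurements are
#'   legitimate for continuous/integer fields unless explicitly reassigned).
#' @return Recoded numeric vector.
#' @export
recode_values <- function(values, coding = NULL,
                          field_type = c("CONTINUOUS", "INTEGER", "CAT_SINGLE", "CAT_MULTIPLE")) {
  field_type <- match.arg(field_type)
  out <- as.numeric(values)
  if (!is.null(coding) && !is.null(coding$reassignments)) {
    idx <- match(out, coding$reassignments$from)
    hit <- !is.na(idx)
    out[hit] <- coding$reassignments$to[idx[hit]]
  }
  if (field_type %in% c("CAT_SINGLE", "CAT_MULTIPLE")) {
    out[!is.na(out) & out < 0] <- NA_real_
  }
  if (!is.null(coding) && !is.null(coding$default_value)) {
    out[is.na(out)] <- coding$default_value
  }
  out
}
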