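# Expansion of categorical (multiple) fields. A participant may hold several
# values for such a field (one per array column); each distinct non-negative
# value becomes its own binary variable: TRUE for the participants holding it,
# FALSE for a comparison group that depends on why an absent value is absent.
#
# The three comparison-group options for value v:
#   OTHER_VALUE_HOLDERS — participants holding some other (non-negative) value;
#   RESPONDERS          — participants holding any value for the field;
#   ALL                 — every participant.
# Regardless of option, a participant whose value set contains a
# missingness-coded (negative) value and who lacks v is set to missing for v:
# the unknown value could have been v, so FALSE cannot be asserted.

#' Expand a categorical (multiple) field into binary variables
#'
#' @param columns The field's array columns at its first instance
#'   (`data.frame`/`data.table`, one column per array index).
#' @param missingness_option How to form the `FALSE` group:
#'   `"OTHER_VALUE_HOLDERS"`, `"RESPONDERS"` or `"ALL"` (see Details).
#' @param coding Optional `phs_data_coding` whose reassignments are applied to
#'   raw values before expansion.
#' @param field_id Field id, used for child naming (`<fieldID>#<value>`).
#' @param validation_only Propagated to every child variable.
#' @return List of `phs_derived` BINARY variables, one per distinct
#'   non-negative observed value, ordered by value.
#' @export
expand_cat_multiple <- function(columns, missingness_option = "RESPONDERS",
                                coding = NULL, field_id = 0L,
                                validation_only = FALSE) {
  missingness_option <- match.arg(missingness_option, CAT_MULT_OPTIONS)
  columns <- data.table::as.data.table(columns)
  keys <- index_columns(names(columns))$keys
  if (nrow(keys) > 0L) {
    first_instance <- min(keys$instance)
    columns <- columns[, keys$column[keys$instance == first_instance], with = FALSE]
  }
  m <- as.matrix(columns)
  if (!is.null(coding) && !is.null(coding$reassignments)) {
    idx <- match(m, coding$reassignments$from)
    hit <- !is.na(idx)
    m[hit] <- coding$reassignments$to[idx[hit]]
  }
  n <- nrow(m)
  responded <- rowSums(!is.na(m)) > 0L
  has_negative <- rowSums(!is.na(m) & m < 0) > 0L
  pos <- m
  pos[!is.na(pos) & pos < 0] <- NA
  holds_some_value <- rowSums(!is.na(pos)) > 0L

  values <- sort(unique(as.vector(pos[!is.na(pos)])))
  if (length(values) == 0L) {
    phs_error("empty_expansion",
              sprintf("field %d has no non-missing non-negative values to expand", field_id))
  }
  in_false_group <- switch(missingness_option,
    OTHER_VALUE_HOLDERS = holds_some_value,
    RESPONDERS = responded,
    ALL = rep(TRUE, n))

  lapply(values, function(v) {
    holds_v <- rowSums(!is.na(pos) & pos == v) > 0L
    child <- rep(NA_real_, n)
    child[in_false_group] <- 0
    # an unknown (negative-coded) value could have been v: FALSE unassertable
    child[has_negative & !holds_v] <- NA_real_
    child[holds_v] <- 1
    derived_variable(
      name = sprintf("%d#%s", field_id, format(v, trim = TRUE)),
      field_id = field_id, data_type = "BINARY", values = child,
      provenance = c(sprintf("field:%d", field_id), "cat-multiple",
                     sprintf("value:%s", format(v, trim = TRUE)),
                     sprintf("false-group:%s", missingness_option)),
      validation_only = validation_only)
  })
}
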