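# First-occurrence selection and array averaging. A field measured at several
# time points (instances) contributes only its first occurrence; continuous
# and integer fields measured several times within that time point (array
# repeats, e.g. spirometry blown two or three times) are averaged per
# participant.

#' Collapse a field's instance/array columns to one vector per participant
#'
#' Only the first measured time point is used: instance 0 when present,
#' otherwise the smallest instance observed (logged). Continuous and integer
#' fields with several array repeats at that instance are averaged over
#' non-missing repeats; a participant with all repeats missing stays missing.
#' Categorical (single) fields must present exactly one array column.
#'
#' @param columns `data.table`/`data.frame` of the field's raw columns, named
#'   `x<field>_<instance>_<array>`.
#' @param field_type The field's declared type.
#' @return List with `values` (numeric vector) and `steps` (provenance labels).
#' @export
collapse_field_columns <- function(columns, field_type) {
  columns <- data.table::as.data.table(columns)
  keys <- index_columns(names(columns))$keys
  phs_assert(nrow(keys) >= 1L, "schema_error", "field has no parseable columns")
  first_instance <- min(keys$instance)
  steps <- character(0)
  if (first_instance != 0L) {
    phs_log("field %d: no instance-0 columns; using instance %d",
            keys$field_id[1], first_instance)
    steps <- c(steps, sprintf("first-instance:%d", first_instance))
  }
  use <- keys[keys$instance == first_instance, ]
  data.table::setorderv(use, "array_index")
  cols <- columns[, use$column, with = FALSE]
  if (ncol(cols) == 1L) {
    return(list(values = as.numeric(cols[[1]]), steps = steps))
  }
  if (field_type == "CAT_SINGLE") {
    phs_error("ambiguous_single",
              sprintf("categorical (single) field %d has %d array columns at instance %d",
                      keys$field_id[1], ncol(cols), first_instance))
  }
  m <- as.matrix(cols)
  vals <- rowMeans(m, na.rm = TRUE)
  vals[!is.finite(vals)] <- NA_real_   # all repeats missing
  list(values = vals, steps = c(steps, sprintf("mean-of-%d-arrays", ncol(cols))))
}
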