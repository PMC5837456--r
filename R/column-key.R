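# Biobank column naming: one column per field/instance/array triple,
# `x<field>_<instance>_<array>`. The instance indexes the time point at which
# a field was measured; the array indexes repeats within a time point (e.g.
# spirometry blown two or three times moments apart).

#' Parse a phenotype column header into its field/instance/array key
#'
#' Biobank phenotype tables name columns `x<fieldID>_<instance>_<array>`:
#' the field is the measured variable, the instance its time point, and the
#' array a repeat within that time point.
#'
#' @param header A single column-header string.
#' @return A list with integer components `field_id`, `instance`,
#'   `array_index`.
#' @examples
#' parse_column_key("x3062_0_1")
#' @export
parse_column_key <- function(header) {
  stopifnot(is.character(header), length(header) == 1L)
  m <- regmatches(header, regexec("^x([0-9]+)_([0-9]+)_([0-9]+)$", header))[[1]]
  if (length(m) != 4L) {
    phs_error("malformed_column",
              sprintf("not a field column header: '%s' (expected x<field>_<instance>_<array>)", header),
              header = header)
  }
  key <- list(field_id = as.integer(m[2]),
              instance = as.integer(m[3]),
              array_index = as.integer(m[4]))
  if (key$field_id <= 0L) {
    phs_error("malformed_column", sprintf("field id must be positive in '%s'", header),
              header = header)
  }
  structure(key, class = "phs_column_key")
}

#' @rdname parse_column_key
#' @param key A column key as returned by [parse_column_key()].
#' @export
format_column_key <- function(key) {
  sprintf("x%d_%d_%d", key$field_id, key$instance, key$array_index)
}

#' @export
format.phs_column_key <- function(x, ...) format_column_key(x)

#' @export
print.phs_column_key <- function(x, ...) {
  cat(format_column_key(x), "\n")
  invisible(x)
}

# Vectorised: data.table of keys for the field columns of a header vector.
# Non-field columns (the participant id, anything else) are returned under
# $other; a header that looks like a field column but is malformed errors.
index_columns <- function(headers) {
  is_field <- grepl("^x[0-9]+_[0-9]+_[0-9]+$", headers)
  keys <- data.table::data.table(
    column = headers[is_field],
    field_id = as.integer(sub("^x([0-9]+)_.*$", "\\1", headers[is_field])),
    instance = as.integer(sub("^x[0-9]+_([0-9]+)_.*$", "\\1", headers[is_field])),
    array_index = as.integer(sub("^x[0-9]+_[0-9]+_([0-9]+)$", "\\1", headers[is_field]))
  )
  list(keys = keys, other = headers[!is_field])
}
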