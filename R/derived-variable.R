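# A derived variable is a processed, test-ready phenotype: the result of
# pushing one raw field (or one value of a multi-valued field) through the
# decision flow. Values are aligned to the dataset's participant order.
#
# data types and their value conventions:
#   CONTINUOUS — finite reals (inverse rank-normal transformed)
#   ORDERED    — integer ranks 1..L from a declared or natural ordering
#   UNORDERED  — >=3 distinct numeric category codes, no order implied
#   BINARY     — exactly 2 distinct non-missing values (0/1)

#' Construct a derived variable
#'
#' @param name Variable name: the field id, with a `#<value>` suffix for the
#'   binary children of categorical (multiple) fields.
#' @param field_id Source field id.
#' @param data_type One of `"CONTINUOUS"`, `"ORDERED"`, `"UNORDERED"`,
#'   `"BINARY"`.
#' @param values Per-participant numeric vector (NA = missing), aligned to the
#'   dataset rows.
#' @param provenance Character vector of processing-step labels, in order.
#' @param validation_only Is the source field flagged as essentially the trait
#'   itself (tested for validation, excluded from the multiple-testing burden)?
#' @return A `phs_derived` object.
#' @export
derived_variable <- function(name, field_id, data_type, values,
                             provenance = character(0), validation_only = FALSE) {
  data_type <- match.arg(data_type, DATA_TYPES)
  distinct <- unique(values[!is.na(values)])
  if (data_type == "BINARY") {
    # a testable binary variable has exactly 2 classes; a single-class vector
    # is representable so the scan can remove and count it as degenerate
    phs_assert(length(distinct) <= 2L, "invalid_derived",
               sprintf("%s: BINARY requires at most 2 distinct values, got %d",
                       name, length(distinct)))
  } else if (data_type == "UNORDERED") {
    phs_assert(length(distinct) >= 3L, "invalid_derived",
               sprintf("%s: UNORDERED requires >=3 distinct values", name))
  } else if (data_type == "CONTINUOUS") {
    phs_assert(all(is.finite(values[!is.na(values)])), "invalid_derived",
               sprintf("%s: CONTINUOUS values must be finite", name))
  }
  structure(list(name = name, field_id = as.integer(field_id),
                 data_type = data_type, values = as.numeric(values),
                 provenance = provenance, validation_only = isTRUE(validation_only)),
            class = "phs_derived")
}

#' @export
print.phs_derived <- function(x, ...) {
  nm <- sum(!is.na(x$values))
  cat(sprintf("derived variable %s [%s]: %d non-missing of %d (%s)\n",
              x$name, x$data_type, nm, length(x$values),
              paste(x$provenance, collapse = " > ")))
  invisible(x)
}

n_distinct_nonmissing <- function(values) {
  length(unique(values[!is.na(values)]))
}
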