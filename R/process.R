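# The decision flow: from a field's declared type (continuous, integer,
# categorical single, categorical multiple) to zero or more test-ready derived
# variables of one of four data types (continuous, ordered, unordered,
# binary). Fields can be removed at defined points (excluded a priori, too few
# distinct values, nothing to expand); a counter object tallies every branch
# so that fields entered = fields emitting variables + fields removed.

new_flow_counters <- function() {
  data.table::data.table(
    fields_entered = 0L, excluded_a_priori = 0L, removed_degenerate = 0L,
    removed_empty_expansion = 0L, removed_error = 0L, fields_emitted = 0L,
    emitted_CONTINUOUS = 0L, emitted_ORDERED = 0L, emitted_UNORDERED = 0L,
    emitted_BINARY = 0L)
}

bump <- function(counters, what, by = 1L) {
  data.table::set(counters, j = what, value = counters[[what]] + as.integer(by))
  invisible(counters)
}

#' Process one field through the decision flow
#'
#' Routing by declared field type:
#' * continuous — first occurrence, array mean, recode, then inverse
#'   rank-normal; heavily tied distributions are binned into 3 ordered
#'   categories instead (2 distinct values make it binary);
#' * integer — as continuous, except 2 distinct values are binary and 3–20
#'   ordered categorical, with only >20 distinct values taking the continuous
#'   path;
#' * categorical (single) — recode under the field's data code; 2 distinct
#'   values are binary, otherwise ordered or unordered as the data code
#'   declares (the declared value ordering supplies the ranks);
#' * categorical (multiple) — expanded into one binary variable per distinct
#'   non-negative value.
#'
#' @param meta One row of the variable-information table (a list or one-row
#'   `data.frame` with `field_id`, `field_type`, `data_code`,
#'   `trait_equivalent`, `cat_mult_missingness`).
#' @param columns The field's raw columns.
#' @param codings Named list of data codings (from [load_data_coding()]).
#' @param seed Run seed; tie-breaking randomness is offset per field id.
#' @param bin_threshold Dominance share routing a continuous-path variable to
#'   binning (see [needs_binning()]).
#' @return List of `phs_derived` variables (possibly empty if the field is
#'   degenerate; see [process_fields()] for the counted version).
#' @export
process_field <- function(meta, columns, codings = list(), seed = 1234L,
                          bin_threshold = 0.2) {
  fid <- as.integer(meta$field_id)
  ftype <- meta$field_type
  vonly <- isTRUE(meta$trait_equivalent)
  coding <- NULL
  if (!is.null(meta$data_code) && !is.na(meta$data_code)) {
    coding <- codings[[as.character(meta$data_code)]]
    if (ftype == "CAT_SINGLE" && is.null(coding)) {
      phs_error("missing_data_code",
                sprintf("field %d: data code %s not found", fid, meta$data_code))
    }
  } else if (ftype == "CAT_SINGLE") {
    phs_error("missing_data_code",
              sprintf("categorical (single) field %d has no data code", fid))
  }

  prov <- sprintf("field:%d", fid)

  if (ftype == "CAT_MULTIPLE") {
    option <- meta$cat_mult_missingness
    if (is.null(option) || is.na(option)) option <- "RESPONDERS"
    return(expand_cat_multiple(columns, option, coding, fid, vonly))
  }

  collapsed <- collapse_field_columns(columns, ftype)
  vals <- recode_values(collapsed$values, coding, ftype)
  prov <- c(prov, collapsed$steps,
            if (!is.null(coding)) sprintf("recode:coding-%d", coding$coding_id))
  d <- n_distinct_nonmissing(vals)
  if (d < 2L) {
    phs_error("degenerate_distribution",
              sprintf("field %d has %d distinct non-missing values", fid, d))
  }

  emit <- function(data_type, values, extra_steps) {
    list(derived_variable(as.character(fid), fid, data_type, values,
                          provenance = c(prov, extra_steps),
                          validation_only = vonly))
  }

  continuous_path <- function(vals, prov_prefix) {
    if (d == 2L) {
      lv <- sort(unique(vals[!is.na(vals)]))
      return(emit("BINARY", match(vals, lv) - 1L, c(prov_prefix, "two-distinct:binary")))
    }
    if (needs_binning(vals, bin_threshold)) {
      b <- bin_to_ordered(vals, 3L)
      emit("ORDERED", b$labels,
           c(prov_prefix, sprintf("binned:k=%d", length(b$counts))))
    } else {
      emit("CONTINUOUS", inverse_rank_normal(vals, field_seed(seed, fid)),
           c(prov_prefix, "irnt"))
    }
  }

  if (ftype == "CONTINUOUS") {
    return(continuous_path(vals, "continuous-field"))
  }

  if (ftype == "INTEGER") {
    route <- classify_integer(vals)
    if (route == "BINARY") {
      lv <- sort(unique(vals[!is.na(vals)]))
      return(emit("BINARY", match(vals, lv) - 1L, "integer:2-distinct"))
    }
    if (route == "ORDERED") {
      lv <- sort(unique(vals[!is.na(vals)]))
      return(emit("ORDERED", match(vals, lv),
                  sprintf("integer:%d-distinct:ordered", d)))
    }
    return(continuous_path(vals, "integer:>20-distinct"))
  }

  # CAT_SINGLE
  if (d == 2L) {
    lv <- sort(unique(vals[!is.na(vals)]))
    return(emit("BINARY", match(vals, lv) - 1L, "cat-single:2-distinct"))
  }
  if (isTRUE(coding$is_ordinal)) {
    if (!is.null(coding$ordering)) {
      ranks <- match(vals, coding$ordering)
      dropped <- sum(!is.na(vals) & is.na(ranks))
      if (dropped > 0L) {
        phs_log("field %d: %d values outside declared ordering set to missing",
                fid, dropped)
      }
      # collapse to the ranks actually observed so levels are 1..L contiguous
      obs_ranks <- sort(unique(ranks[!is.na(ranks)]))
      ranks <- match(ranks, obs_ranks)
    } else {
      lv <- sort(unique(vals[!is.na(vals)]))
      ranks <- match(vals, lv)
    }
    if (n_distinct_nonmissing(ranks) == 2L) {
      return(emit("BINARY", ranks - min(ranks, na.rm = TRUE), "cat-single:ordered->binary"))
    }
    return(emit("ORDERED", ranks, "cat-single:ordered"))
  }
  emit("UNORDERED", vals, "cat-single:unordered")
}

#' Process a set of fields with flow accounting
#'
#' Runs [process_field()] over a variable-information table against a dataset,
#' removing excluded and degenerate fields with per-branch counts. Field-level
#' conservation holds on every run: `fields_entered = fields_emitted +
#' excluded_a_priori + removed_degenerate + removed_empty_expansion +
#' removed_error`.
#'
#' @param dataset A `phs_dataset` from [assemble_dataset()].
#' @param variable_info Variable-information table ([load_variable_info()]).
#' @param codings Data codings ([load_data_coding()]).
#' @param seed Run seed for tie-breaking randomness.
#' @param bin_threshold See [needs_binning()].
#' @return List with `derived` (list of `phs_derived`) and `counters`.
#' @export
process_fields <- function(dataset, variable_info, codings = list(),
                           seed = 1234L, bin_threshold = 0.2) {
  counters <- new_flow_counters()
  derived <- list()
  present <- unique(dataset$columns$field_id)
  vi <- variable_info[field_id %in% present]
  skipped <- setdiff(present, vi$field_id)
  if (length(skipped) > 0L) {
    phs_log("no variable-info row for field(s) %s; skipped",
            paste(skipped, collapse = ", "))
  }
  for (i in seq_len(nrow(vi))) {
    meta <- vi[i]
    bump(counters, "fields_entered")
    if (isTRUE(meta$excluded)) {
      bump(counters, "excluded_a_priori")
      phs_log("field %d: excluded a priori", meta$field_id)
      next
    }
    dvs <- tryCatch(
      process_field(meta, field_columns(dataset, meta$field_id), codings,
                    seed = seed, bin_threshold = bin_threshold),
      phs_degenerate_distribution = function(e) {
        bump(counters, "removed_degenerate")
        phs_log("field %d: removed (%s)", meta$field_id, conditionMessage(e))
        NULL
      },
      phs_empty_expansion = function(e) {
        bump(counters, "removed_empty_expansion")
        phs_log("field %d: removed (%s)", meta$field_id, conditionMessage(e))
        NULL
      },
      phenomescan_error = function(e) {
        bump(counters, "removed_error")
        phs_log("field %d: removed (%s)", meta$field_id, conditionMessage(e))
        NULL
      })
    if (is.null(dvs)) next
    bump(counters, "fields_emitted")
    for (dv in dvs) bump(counters, paste0("emitted_", dv$data_type))
    derived <- c(derived, dvs)
  }
  phs_log("processed %d fields -> %d derived variables",
          counters$fields_entered, length(derived))
  list(derived = derived, counters = counters)
}
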