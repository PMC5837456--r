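# Assembly of the analysis dataset: phenotype table, trait of interest and
# confounders, joined one row per participant. The trait and confounders may
# live in the phenotype file itself or in separate files keyed on the same
# participant id; both routes must produce cell-identical datasets.

#' Assemble the analysis dataset
#'
#' Joins the phenotype table with the trait of interest and any confounders on
#' the participant id (strict inner join: a participant absent from any
#' supplied file is dropped, and participants missing the trait are dropped
#' globally since the trait enters every regression).
#'
#' @param pheno Path to the phenotype CSV (`userId` + `x<field>_<instance>_<array>`
#'   columns; empty cell = missing), or a `data.frame` of the same shape.
#' @param trait Either the name of a trait column inside `pheno`, or a path /
#'   `data.frame` holding the id column plus one trait column.
#' @param confounders Optional path / `data.frame` with the id column plus one
#'   column per confounder, or a character vector naming confounder columns
#'   inside `pheno` (combined-file route); `NULL` means no confounder file
#'   (defaults apply downstream).
#' @param id_col Participant id column name shared by all files (default
#'   `"userId"`).
#' @param trait_col Trait column name when `trait` is a file or table with
#'   several columns; by default the single non-id column.
#' @return A `phs_dataset`: list with `participant_id`, `trait` (numeric),
#'   `trait_name`, `confounders` (data.table, zero columns if none), and
#'   `phenotypes` (data.table of raw field columns).
#' @export
assemble_dataset <- function(pheno, trait, confounders = NULL,
                             id_col = "userId", trait_col = NULL) {
  ph <- read_table_arg(pheno)
  phs_assert(id_col %in% names(ph), "schema_error",
             sprintf("phenotype table has no id column '%s'", id_col))
  check_unique_ids(ph, id_col, "phenotype file")

  # trait: column-in-pheno or separate table
  if (is.character(trait) && length(trait) == 1L && trait %in% names(ph)) {
    trait_name <- trait
    tr <- ph[, c(id_col, trait_name), with = FALSE]
    ph[[trait_name]] <- NULL
  } else {
    tr <- read_table_arg(trait)
    phs_assert(id_col %in% names(tr), "schema_error",
               sprintf("trait table has no id column '%s'", id_col))
    check_unique_ids(tr, id_col, "trait file")
    trait_name <- trait_col %||% setdiff(names(tr), id_col)[1]
    phs_assert(!is.na(trait_name) && trait_name %in% names(tr), "schema_error",
               "trait column not found in trait table")
    tr <- tr[, c(id_col, trait_name), with = FALSE]
  }

  cf <- NULL
  if (is.character(confounders) && all(confounders %in% names(ph))) {
    # confounders live in the combined phenotype file
    cf <- ph[, c(id_col, confounders), with = FALSE]
    ph <- ph[, setdiff(names(ph), confounders), with = FALSE]
    confounders <- NULL
  }
  if (!is.null(confounders)) {
    cf <- read_table_arg(confounders)
    phs_assert(id_col %in% names(cf), "schema_error",
               sprintf("confounder table has no id column '%s'", id_col))
    check_unique_ids(cf, id_col, "confounder file")
    phs_assert(!(trait_name %in% setdiff(names(cf), id_col)), "schema_error",
               "trait of interest may not appear among the confounders")
  }

  merged <- merge(ph, tr, by = id_col)
  if (!is.null(cf)) merged <- merge(merged, cf, by = id_col)
  # drop participants with a missing trait: required for every regression
  merged <- merged[!is.na(merged[[trait_name]])]
  phs_assert(nrow(merged) > 0L, "empty_join",
             "no participants shared by all input files with a non-missing trait")
  data.table::setorderv(merged, id_col)

  cols <- index_columns(names(merged))
  conf_names <- if (is.null(cf)) character(0) else setdiff(names(cf), id_col)
  ds <- structure(list(
    participant_id = merged[[id_col]],
    trait = as.numeric(merged[[trait_name]]),
    trait_name = trait_name,
    confounders = merged[, conf_names, with = FALSE],
    phenotypes = merged[, cols$keys$column, with = FALSE],
    columns = cols$keys
  ), class = "phs_dataset")
  phs_log("assembled dataset: %d participants, %d field columns (%d fields), %d confounders",
          nrow(merged), nrow(cols$keys), length(unique(cols$keys$field_id)),
          length(conf_names))
  ds
}

read_table_arg <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    phs_assert(file.exists(x), "io_error", sprintf("input file not found: %s", x))
    dt <- data.table::fread(x, header = TRUE, na.strings = c("", "NA"))
  } else {
    dt <- data.table::as.data.table(x)
  }
  dt
}

check_unique_ids <- function(dt, id_col, what) {
  dup <- dt[[id_col]][duplicated(dt[[id_col]])]
  phs_assert(length(dup) == 0L, "duplicate_participant",
             sprintf("duplicated participant id(s) in %s: %s", what,
                     paste(utils::head(unique(dup), 5L), collapse = ", ")))
}

#' @export
print.phs_dataset <- function(x, ...) {
  cat(sprintf("phenome-scan dataset: %d participants, %d fields (%d columns), trait '%s', %d confounders\n",
              length(x$participant_id), length(unique(x$columns$field_id)),
              nrow(x$columns), x$trait_name, ncol(x$confounders)))
  invisible(x)
}

# columns (data.table subset) for one field
field_columns <- function(dataset, fid) {
  keys <- dataset$columns[field_id == fid]
  dataset$phenotypes[, keys$column, with = FALSE]
}
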