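# End-to-end scan runner and job partitioning. Phenome scans parallelise
# naturally: fields are split into contiguous parts by sorted field id, each
# part is scanned as an independent job, and a merge step recomputes the
# ranking and the Bonferroni threshold over the combined results (the
# multiple-testing count must be finalised at merge time — per-part counts
# would distort the threshold).

#' Partition fields into balanced contiguous parts
#'
#' Deterministic: fields are sorted by id and split into `num_parts`
#' contiguous blocks whose sizes differ by at most one. Parts are disjoint and
#' their union is the input.
#'
#' @param fields Vector of field ids.
#' @param num_parts Number of parts (>= 1).
#' @param part_index Which part to return (1-based).
#' @return Sorted vector of the part's field ids.
#' @export
partition_fields <- function(fields, num_parts, part_index) {
  phs_assert(num_parts >= 1L, "config_error", "num_parts must be >= 1")
  phs_assert(part_index >= 1L && part_index <= num_parts, "config_error",
             sprintf("part_index %d out of range 1..%d", part_index, num_parts))
  fields <- sort(unique(fields))
  sizes <- rep(length(fields) %/% num_parts, num_parts)
  extra <- length(fields) %% num_parts
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ends <- cumsum(sizes)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  if (sizes[part_index] == 0L) return(fields[0])
  fields[starts[part_index]:ends[part_index]]
}

#' Build a run configuration
#'
#' @param phenofile Phenotype CSV path.
#' @param traitofinterestfile Trait file path, or `NULL` if the trait is a
#'   column of the phenotype file.
#' @param confounderfile Optional confounder file path.
#' @param variablelistfile Variable-information TSV path.
#' @param datacodingfile Data-coding TSV path.
#' @param resdir Results directory (created if needed).
#' @param userid_col Participant id column (default `"userId"`).
#' @param trait_col Trait column name (default: the trait file's single
#'   non-id column).
#' @param genetic Is the trait genetic (adds the genotype-chip confounder to
#'   the defaults)?
#' @param categoriesfile,fieldmapfile Optional hierarchy files enabling the
#'   visualization JSON export.
#' @param num_parts,part_index Job partitioning (defaults: one part).
#' @param alpha Family-wise level (default 0.05).
#' @param seed Run seed for tie-breaking randomness (default 1234).
#' @param save_derived Also write the derived (test-ready) variables and their
#'   provenance, for customised downstream analysis?
#' @return A `phs_run_config`.
#' @export
run_config <- function(phenofile, traitofinterestfile = NULL,
                       confounderfile = NULL, variablelistfile,
                       datacodingfile, resdir, userid_col = "userId",
                       trait_col = NULL, genetic = FALSE,
                       categoriesfile = NULL, fieldmapfile = NULL,
                       num_parts = 1L, part_index = 1L, alpha = 0.05,
                       seed = 1234L, save_derived = FALSE) {
  phs_assert(num_parts >= 1L && part_index >= 1L && part_index <= num_parts,
             "config_error", "need 1 <= part_index <= num_parts")
  structure(list(phenofile = phenofile,
                 traitofinterestfile = traitofinterestfile,
                 confounderfile = confounderfile,
                 variablelistfile = variablelistfile,
                 datacodingfile = datacodingfile, resdir = resdir,
                 userid_col = userid_col, trait_col = trait_col,
                 genetic = isTRUE(genetic),
                 categoriesfile = categoriesfile, fieldmapfile = fieldmapfile,
                 num_parts = as.integer(num_parts),
                 part_index = as.integer(part_index), alpha = alpha,
                 seed = as.integer(seed), save_derived = isTRUE(save_derived)),
            class = "phs_run_config")
}

#' Run a phenome scan
#'
#' Loads the inputs, processes the selected part's fields through the decision
#' flow, runs the association scan, and writes the part's results. A
#' single-part run (or a merge of all parts, see [merge_scan_parts()]) also
#' writes the ranked results table, the QQ plot, the forest plots and — when a
#' hierarchy is supplied — the visualization JSON.
#'
#' @param config A `phs_run_config`.
#' @return For a single-part run, a `phs_scan_results` (invisibly, with
#'   `counters` attached as an attribute); for a multi-part run, the part's
#'   raw result table.
#' @export
run_phenome_scan <- function(config) {
  stopifnot(inherits(config, "phs_run_config"))
  for (p in c(config$phenofile, config$traitofinterestfile, config$confounderfile,
              config$variablelistfile, config$datacodingfile)) {
    phs_assert(file.exists(p), "io_error", sprintf("input file not found: %s", p))
  }
  dir.create(config$resdir, showWarnings = FALSE, recursive = TRUE)
  phs_open_log(file.path(config$resdir,
                         sprintf("scan-part%d-of-%d.log", config$part_index,
                                 config$num_parts)))
  on.exit(phs_close_log())
  phs_log("run: seed=%d alpha=%s parts=%d/%d genetic=%s", config$seed,
          format(config$alpha), config$part_index, config$num_parts,
          config$genetic)

  vi <- load_variable_info(config$variablelistfile)
  codings <- load_data_coding(config$datacodingfile)
  trait_arg <- config$traitofinterestfile %||% config$trait_col
  dataset <- assemble_dataset(config$phenofile, trait_arg,
                              confounders = config$confounderfile,
                              id_col = config$userid_col,
                              trait_col = config$trait_col)
  conf_names <- if (is.null(config$confounderfile)) NULL
                else names(dataset$confounders)
  spec <- model_spec(dataset$trait_name, conf_names, genetic = config$genetic)

  part_ids <- partition_fields(intersect(vi$field_id, dataset$columns$field_id),
                               config$num_parts, config$part_index)
  vi_part <- vi[field_id %in% part_ids]
  processed <- process_fields(dataset, vi_part, codings, seed = config$seed)
  if (config$save_derived) save_derived_variables(processed$derived, dataset, config$resdir)
  scan <- run_scan(processed$derived, dataset, spec)

  part_path <- file.path(config$resdir,
                         sprintf("results-part%d-of-%d.tsv", config$part_index,
                                 config$num_parts))
  data.table::fwrite(scan$results, part_path, sep = "\t", na = "", quote = FALSE)
  counters <- cbind(processed$counters, scan$counters)
  data.table::fwrite(counters,
                     file.path(config$resdir,
                               sprintf("flow-counts-part%d-of-%d.tsv",
                                       config$part_index, config$num_parts)),
                     sep = "\t")

  if (config$num_parts > 1L) {
    message(sprintf(
      "part %d/%d written to %s; after all parts finish, combine with merge_scan_parts(\"%s\", alpha = %s)",
      config$part_index, config$num_parts, part_path, config$resdir,
      format(config$alpha)))
    return(invisible(scan$results))
  }
  ranked <- finalize_outputs(scan$results, config)
  attr(ranked, "counters") <- counters
  invisible(ranked)
}

#' Merge the per-part results of a partitioned scan
#'
#' Concatenates all `results-part*.tsv` files in `resdir`, then recomputes the
#' ranking and the Bonferroni threshold over the merged set and writes the
#' final outputs. Row contents (p-values, estimates, flags) are untouched, so
#' a merged multi-part scan equals a single-part scan row for row.
#'
#' @param resdir Directory holding the per-part result files.
#' @param config Optional `phs_run_config` (for alpha and hierarchy paths);
#'   alternatively pass `alpha`.
#' @param alpha Family-wise level when no config is given.
#' @return A `phs_scan_results`, invisibly.
#' @export
merge_scan_parts <- function(resdir, config = NULL, alpha = 0.05) {
  files <- sort(list.files(resdir, pattern = "^results-part[0-9]+-of-[0-9]+\\.tsv$",
                           full.names = TRUE))
  phs_assert(length(files) >= 1L, "io_error",
             sprintf("no per-part result files in %s", resdir))
  n_parts <- unique(as.integer(sub(".*-of-([0-9]+)\\.tsv$", "\\1", files)))
  phs_assert(length(n_parts) == 1L && length(files) == n_parts, "config_error",
             sprintf("expected %s part files, found %d",
                     paste(n_parts, collapse = "/"), length(files)))
  results <- data.table::rbindlist(lapply(files, data.table::fread, sep = "\t",
                                          na.strings = "",
                                          colClasses = list(character = "varName")))
  if (is.null(config)) {
    config <- list(resdir = resdir, alpha = alpha, categoriesfile = NULL,
                   fieldmapfile = NULL)
  }
  invisible(finalize_outputs(results, config))
}

# ranking, threshold and the result artefacts (table, plots, viz JSON)
finalize_outputs <- function(results, config) {
  ranked <- rank_and_threshold(results, alpha = config$alpha)
  write_results_table(ranked, file.path(config$resdir, "results.tsv"))
  save_qq_plot(ranked, file.path(config$resdir, "qq.pdf"))
  save_forest_plots(ranked, config$resdir)
  if (!is.null(config$categoriesfile) && !is.null(config$fieldmapfile)) {
    hierarchy <- load_hierarchy(config$categoriesfile, config$fieldmapfile)
    export_viz_json(ranked, hierarchy, file.path(config$resdir, "viz-results.json"))
  }
  ranked
}

# derived-variable export: one CSV of participant-level values plus a TSV
# provenance log, enabling customised re-analysis outside the engine
save_derived_variables <- function(derived, dataset, resdir) {
  if (length(derived) == 0L) return(invisible(NULL))
  out <- data.table::data.table(userId = dataset$participant_id)
  for (dv in derived) out[[dv$name]] <- dv$values
  data.table::fwrite(out, file.path(resdir, "derived-variables.csv"), na = "",
                     quote = FALSE)
  prov <- data.table::rbindlist(lapply(derived, function(dv) {
    data.table::data.table(varName = dv$name, field_id = dv$field_id,
                           data_type = dv$data_type,
                           provenance = paste(dv$provenance, collapse = " > "))
  }))
  data.table::fwrite(prov, file.path(resdir, "derived-provenance.tsv"), sep = "\t")
  invisible(NULL)
}
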