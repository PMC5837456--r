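# Export of scan results as a hierarchical JSON document for interactive
# visualization. Phenotypes are organised under the biobank's hierarchical
# field-category tree; each tested variable becomes a leaf under its field's
# category, carrying its p-value, estimate (null for unordered results), data
# type and threshold status. The document structure is described by the schema
# shipped at inst/schema/viz-results.schema.json.
#
# Hierarchy file dialects (tab-separated, header row):
#   categories:        category_id  parent_id  title   (parent_id NA = root)
#   field-to-category: field_id  category_id

#' Load the category hierarchy
#'
#' @param categories_path TSV with columns `category_id`, `parent_id`
#'   (`NA` for the root), `title`.
#' @param field_map_path TSV with columns `field_id`, `category_id`.
#' @return A `phs_hierarchy`: list of `categories` and `field_map` tables,
#'   validated to form a tree (single root, no cycles).
#' @export
load_hierarchy <- function(categories_path, field_map_path) {
  cats <- data.table::fread(categories_path, sep = "\t", header = TRUE,
                            na.strings = "NA")
  fmap <- data.table::fread(field_map_path, sep = "\t", header = TRUE,
                            na.strings = "NA")
  phs_assert(all(c("category_id", "parent_id", "title") %in% names(cats)),
             "schema_error", "category file needs category_id, parent_id, title")
  phs_assert(all(c("field_id", "category_id") %in% names(fmap)),
             "schema_error", "field map needs field_id, category_id")
  validate_hierarchy(cats)
  structure(list(categories = cats, field_map = fmap), class = "phs_hierarchy")
}

validate_hierarchy <- function(cats) {
  roots <- cats[is.na(parent_id), category_id]
  phs_assert(length(roots) == 1L, "invalid_hierarchy",
             sprintf("hierarchy must have exactly one root, found %d", length(roots)))
  phs_assert(!anyDuplicated(cats$category_id), "invalid_hierarchy",
             "duplicate category ids")
  phs_assert(!any(!is.na(cats$parent_id) & cats$parent_id == cats$category_id),
             "invalid_hierarchy", "a category may not be its own parent")
  phs_assert(all(stats::na.omit(cats$parent_id) %in% cats$category_id),
             "invalid_hierarchy", "parent id not among category ids")
  # cycle check: walk up from every node; depth cannot exceed node count
  parent_of <- stats::setNames(cats$parent_id, as.character(cats$category_id))
  for (cid in cats$category_id) {
    seen <- 0L
    cur <- cid
    while (!is.na(cur)) {
      seen <- seen + 1L
      phs_assert(seen <= nrow(cats), "invalid_hierarchy",
                 sprintf("cycle in hierarchy at category %d", cid))
      cur <- parent_of[[as.character(cur)]]
    }
  }
  invisible(TRUE)
}

#' Export scan results as hierarchical visualization JSON
#'
#' Builds the category tree and attaches each tested variable as a leaf under
#' its field's category; fields without a category mapping are attached to the
#' root (logged). Leaves carry `name`, `field_id`, `p`, `estimate` (null when
#' absent), `data_type` and `below_threshold`; the root carries the scan-level
#' `m_tests`, `alpha` and `threshold`.
#'
#' @param scan A `phs_scan_results`.
#' @param hierarchy A `phs_hierarchy` from [load_hierarchy()].
#' @param path Output JSON path.
#' @return The path, invisibly.
#' @export
export_viz_json <- function(scan, hierarchy, path) {
  cats <- hierarchy$categories
  validate_hierarchy(cats)
  res <- scan$results
  cat_of <- stats::setNames(hierarchy$field_map$category_id,
                            as.character(hierarchy$field_map$field_id))
  root_id <- cats[is.na(parent_id), category_id]
  assigned <- cat_of[as.character(res$field_id)]
  unmapped <- is.na(assigned)
  if (any(unmapped)) {
    phs_log("viz export: %d variable(s) without a category mapping attached to root",
            sum(unmapped))
    assigned[unmapped] <- root_id
  }

  leaf <- function(i) {
    list(name = res$varName[i],
         field_id = res$field_id[i],
         p = res$p_value[i],
         estimate = if (is.na(res$estimate[i])) NULL else res$estimate[i],
         data_type = res$data_type[i],
         below_threshold = res$below_threshold[i])
  }
  build <- function(cid) {
    kids <- cats[!is.na(parent_id) & parent_id == cid, category_id]
    vars_here <- which(assigned == cid)
    node <- list(category_id = cid,
                 title = cats[category_id == cid, title],
                 children = lapply(kids, build),
                 variables = lapply(vars_here, leaf))
    node
  }
  doc <- build(root_id)
  doc$scan <- list(m_tests = scan$m_tests, alpha = scan$alpha,
                   threshold = scan$threshold)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(path)
}

#' Structurally validate a visualization JSON document
#'
#' Checks the emitted document against the shipped schema's structural rules:
#' every node has `category_id`, `title`, `children`, `variables`; every leaf
#' has `name`, `field_id`, `p`, `data_type`, `below_threshold`; the root adds
#' the `scan` block.
#'
#' @param path Path to a JSON file written by [export_viz_json()].
#' @return `TRUE` invisibly; errors with class `phs_invalid_hierarchy` on a
#'   malformed document.
#' @export
validate_viz_json <- function(path) {
  doc <- jsonlite::read_json(path)
  phs_assert(all(c("m_tests", "alpha", "threshold") %in% names(doc$scan)),
             "invalid_hierarchy", "root node missing scan block")
  check_node <- function(node) {
    phs_assert(all(c("category_id", "title", "children", "variables") %in% names(node)),
               "invalid_hierarchy", "category node missing required keys")
    for (v in node$variables) {
      phs_assert(all(c("name", "field_id", "p", "data_type", "below_threshold") %in% names(v)),
                 "invalid_hierarchy", "variable leaf missing required keys")
    }
    for (child in node$children) check_node(child)
  }
  check_node(doc)
  invisible(TRUE)
}
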