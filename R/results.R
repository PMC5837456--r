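# Ranking, multiple-testing correction and the results artefacts. Results are
# ranked by ascending p-value; the family-wise threshold is alpha divided by
# the number of tests counted towards the multiple-testing burden —
# validation-only results (fields flagged a priori as aspects of the trait
# itself) are tested but excluded from that count, as are non-converged
# results with no p-value.

#' Rank scan results and apply the Bonferroni threshold
#'
#' @param results Result table from [run_scan()].
#' @param alpha Family-wise significance level (default 0.05).
#' @return A `phs_scan_results`: list with `results` (stably sorted by
#'   ascending p, ties by field id then name, annotated `below_threshold`),
#'   `m_tests` (non-validation results with a p-value), `alpha` and
#'   `threshold = alpha / m_tests`. `below_threshold` is strict:
#'   `p < threshold`.
#' @export
rank_and_threshold <- function(results, alpha = 0.05) {
  results <- data.table::copy(data.table::as.data.table(results))
  m <- results[validation_only == FALSE & !is.na(p_value), .N]
  phs_assert(m >= 1L, "no_tests",
             "no countable tests: every result is validation-only or has no p-value")
  threshold <- alpha / m
  data.table::setorderv(results, c("p_value", "field_id", "varName"),
                        na.last = TRUE)
  results[, below_threshold := !is.na(p_value) & p_value < threshold]
  phs_log("ranked %d results; %d tests counted; threshold %s = %s/%d",
          nrow(results), m, format(signif(threshold, 3)), format(alpha), m)
  structure(list(results = results[], m_tests = m, alpha = alpha,
                 threshold = threshold),
            class = "phs_scan_results")
}

#' @export
print.phs_scan_results <- function(x, ...) {
  cat(sprintf("phenome scan: %d results, %d counted tests, threshold %s (alpha %s); %d below threshold\n",
              nrow(x$results), x$m_tests, format(signif(x$threshold, 3)),
              format(x$alpha), sum(x$results$below_threshold)))
  invisible(x)
}

#' Expected and observed -log10 p sequences for a QQ plot
#'
#' Observed points are the sorted \eqn{-\log_{10} p}; expected points are
#' \eqn{-\log_{10}((i - 0.5)/m)} for ranks \eqn{i = 1..m} — the uniform
#' quantiles a null scan would produce.
#'
#' @param results Result table (or a `phs_scan_results`); rows without a
#'   p-value are ignored.
#' @return `data.table` with columns `expected` and `observed`, both
#'   increasing.
#' @export
qq_points <- function(results) {
  if (inherits(results, "phs_scan_results")) results <- results$results
  p <- sort(results$p_value[!is.na(results$p_value)])
  phs_assert(length(p) >= 1L, "no_tests", "no p-values to plot")
  m <- length(p)
  data.table::data.table(
    expected = -log10(((m:1) - 0.5) / m),
    observed = -log10(rev(p)))
}

#' Plot tables for the forest plots of below-threshold results
#'
#' One table per estimating data type: continuous (coefficients on the SD
#' scale), ordered and binary (odds ratios), each with 95% CI bounds.
#' Unordered results carry no overall estimate (their p-value is a
#' likelihood-ratio model test), so no forest table is produced for them.
#'
#' @param scan A `phs_scan_results`.
#' @return Named list of `data.table`s: `continuous`, `ordered`, `binary`.
#' @export
forest_data <- function(scan) {
  below <- scan$results[below_threshold == TRUE]
  sel <- function(type) {
    below[data_type == type,
          .(varName, field_id, n, estimate, ci_lower, ci_upper, p_value)]
  }
  list(continuous = sel("CONTINUOUS"), ordered = sel("ORDERED"),
       binary = sel("BINARY"))
}

#' Write the ranked results table
#'
#' Tab-separated, deterministic ordering (the ranking), full-precision
#' p-values; unordered results have empty estimate/CI cells.
#'
#' @param scan A `phs_scan_results`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_results_table <- function(scan, path) {
  dir_ok <- dir.exists(dirname(path))
  phs_assert(dir_ok, "io_error", sprintf("directory does not exist: %s", dirname(path)))
  out <- scan$results[, .(varName, field_id, data_type, n, estimate, ci_lower,
                          ci_upper, p_value, below_threshold, validation_only,
                          converged)]
  data.table::fwrite(out, path, sep = "\t", na = "", quote = FALSE)
  invisible(path)
}

#' Read back a results table written by [write_results_table()]
#'
#' @param path Path to a results TSV.
#' @return `data.table` of results.
#' @export
read_results_table <- function(path) {
  data.table::fread(path, sep = "\t", header = TRUE, na.strings = "")
}
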