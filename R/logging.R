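# Per-run log. A scan writes row/column counts, rejected records and per-field
# notices to a plain-text log file; `phs_log()` is a no-op when no log is open,
# so library use stays quiet.

.phs_state <- new.env(parent = emptyenv())

#' Open a run log file
#'
#' All readers and the scan loop append notices (row/column counts, rejected
#' records, removed fields) to the active log. Closing restores quiet
#' operation.
#'
#' @param path File to append log lines to; its directory must exist.
#' @return The path, invisibly.
#' @export
phs_open_log <- function(path) {
  .phs_state$log_path <- path
  cat(sprintf("# phenomescan log opened %s\n", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
      file = path, append = FALSE)
  invisible(path)
}

#' @rdname phs_open_log
#' @export
phs_close_log <- function() {
  .phs_state$log_path <- NULL
  invisible(NULL)
}

phs_log <- function(fmt, ...) {
  path <- .phs_state$log_path
  if (!is.null(path)) {
    cat(sprintf(paste0(fmt, "\n"), ...), file = path, append = TRUE)
  }
  invisible(NULL)
}
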