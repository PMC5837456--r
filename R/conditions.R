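# Structured error conditions. Every engine error carries a class of the form
# "phs_<kind>" plus "phenomescan_error", so callers (and the scan loop, which
# must never abort on a single field) can dispatch on the failure kind.

phs_error <- function(kind, message, ...) {
  stop(errorCondition(
    message,
    ...,
    class = c(paste0("phs_", kind), "phenomescan_error", "error")
  ))
}

phs_assert <- function(ok, kind, message, ...) {
  if (!isTRUE(ok)) phs_error(kind, message, ...)
  invisible(TRUE)
}
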