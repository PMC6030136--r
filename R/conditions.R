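#' @keywords internal
"_PACKAGE"

# Structured conditions so callers (and the CLI) can distinguish failure
# classes. All inherit from "cmx_error".
cmx_abort <- function(message, class, ..., call = sys.call(-1)) {
  stop(structure(
    class = c(class, "cmx_error", "error", "condition"),
    list(message = message, call = call, ...)
  ))
}

cmx_format_error <- function(message, ...) {
  cmx_abort(message, "cmx_format_error", ...)
}

cmx_not_found_error <- function(message, query = NULL, ...) {
  cmx_abort(message, "cmx_not_found_error", query = query, ...)
}

cmx_ambiguity_error <- function(message, candidates = NULL, ...) {
  cmx_abort(message, "cmx_ambiguity_error", candidates = candidates, ...)
}

cmx_contract_error <- function(message, ...) {
  cmx_abort(message, "cmx_contract_error", ...)
}

cmx_domain_error <- function(message, ...) {
  cmx_abort(message, "cmx_domain_error", ...)
}

cmx_config_error <- function(message, ...) {
  cmx_abort(message, "cmx_config_error", ...)
}

cmx_io_error <- function(message, ...) {
  cmx_abort(message, "cmx_io_error", ...)
}

# Logging goes to stderr so result streams stay clean.
cmx_log <- function(fmt, ..., verbose = getOption("chemmix.verbose", TRUE)) {
  if (isTRUE(verbose)) {
    message(sprintf(fmt, ...))
  }
  invisible(NULL)
}
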