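# Condition classes shared across the package.
#
# Two user-visible failure classes drive the CLI exit-code contract:
#   pn_usage_error -- bad invocation (missing flag, unknown subcommand)
#   pn_data_error  -- malformed or inconsistent input data

stop_usage <- function(msg, ...) {
  stop(structure(
    class = c("pn_usage_error", "pn_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = NULL)
  ))
}

stop_data <- function(msg, ..., line = NULL) {
  text <- sprintf(msg, ...)
  if (!is.null(line)) text <- sprintf("line %d: %s", line, text)
  stop(structure(
    class = c("pn_data_error", "pn_error", "error", "condition"),
    list(message = text, call = NULL, line = line)
  ))
}

warn_pn <- function(msg, ...) {
  warning(sprintf(msg, ...), call. = FALSE)
}
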