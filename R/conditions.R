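# Condition helpers: usage errors (bad arguments) vs data errors (bad input
# content) are distinguished so the CLI can map them to distinct exit codes.

abort_usage <- function(msg, call = sys.call(-1)) {
  stop(structure(
    class = c("aerateCT_usage_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

abort_data <- function(msg, call = sys.call(-1)) {
  stop(structure(
    class = c("aerateCT_data_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
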