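# Classed conditions so the CLI can map error families to exit codes.

mta_abort <- function(message, class, ...) {
  stop(errorCondition(message, ..., class = c(class, "mta_error")))
}

parse_error <- function(message, offset = NA_integer_) {
  msg <- if (is.na(offset)) message else sprintf("%s (at character %d)", message, offset)
  mta_abort(msg, "mta_parse_error", offset = offset)
}

format_error <- function(message, line = NA_integer_) {
  msg <- if (is.na(line)) message else sprintf("%s (line %d)", message, line)
  mta_abort(msg, "mta_format_error", line = line)
}

annotation_error <- function(message) {
  mta_abort(message, "mta_annotation_error")
}

usage_error <- function(message) {
  mta_abort(message, "mta_usage_error")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
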