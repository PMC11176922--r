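# Condition helpers: every user-facing failure mode has a stable class so
# callers (and the test suite) can match on it rather than on message text.

bc_abort <- function(class, message, ...) {
  abort(message, class = c(class, "breathecast_error"), ...)
}

bc_parse_error <- function(message, line = NA_integer_) {
  bc_abort("bc_parse_error", message, line = line)
}
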