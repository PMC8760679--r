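# Classed conditions so callers (and tests) can distinguish malformed input
# files from violated function contracts.

abort_format <- function(msg, call. = FALSE) {
  stop(structure(
    class = c("reactcap_format_error", "error", "condition"),
    list(message = msg, call = if (isTRUE(call.)) sys.call(-1) else NULL)
  ))
}

abort_contract <- function(msg, call. = FALSE) {
  stop(structure(
    class = c("reactcap_contract_error", "error", "condition"),
    list(message = msg, call = if (isTRUE(call.)) sys.call(-1) else NULL)
  ))
}
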