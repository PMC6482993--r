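# Structured error conditions so callers and tests can discriminate failure
# modes without matching message strings.

abort_oir <- function(message, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "oir_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
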