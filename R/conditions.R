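# Classed conditions so callers (and tests) can distinguish failure modes.

glyconact_error <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "glyconact_error"),
                      call = call))
}

glyconact_warning <- function(msg, class) {
  warning(warningCondition(msg, class = c(class, "glyconact_warning")))
}
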