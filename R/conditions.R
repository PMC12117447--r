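# Classed conditions so callers can distinguish failure modes programmatically.

abort <- function(message, class, call = sys.call(-1), ...) {
  stop(errorCondition(message, ..., class = c(class, "mesosaxs_error")))
}

warn <- function(message, class) {
  warning(warningCondition(message, class = c(class, "mesosaxs_warning")))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
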