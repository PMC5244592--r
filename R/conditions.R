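# Classed conditions so callers (and the CLI) can distinguish bad input
# (exit code 2) from numerical failure (exit code 3).

stop_input <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("vbsnv_input_error", "vbsnv_error")))
}

stop_numeric <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("vbsnv_numeric_error", "vbsnv_error")))
}

stop_undefined_test <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("vbsnv_undefined_test", "vbsnv_error")))
}

warn_vbsnv <- function(msg, ...) {
  warning(warningCondition(sprintf(msg, ...), class = "vbsnv_warning"))
}
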