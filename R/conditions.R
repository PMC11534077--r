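# Condition constructors shared across the package.
#
# Three classes are distinguished so the command-line front end can map
# them onto exit codes: format errors (malformed input files), validation
# errors (well-formed input that violates an invariant), and usage errors
# (bad flags / arguments).  All inherit from "ap_error".

ap_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "ap_error"), call = call))
}

stop_format <- function(msg) ap_stop(msg, "ap_format_error")
stop_validation <- function(msg) ap_stop(msg, "ap_validation_error")
stop_usage <- function(msg) ap_stop(msg, "ap_usage_error")

ap_warn <- function(msg, class = "ap_warning") {
  warning(warningCondition(msg, class = c(class, "ap_warning")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
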