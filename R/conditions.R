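# Structured error conditions so callers can test failure modes by class
# rather than by message text.

stop_pulsebp <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "pulsebp_error"), call = call))
}

stop_invalid <- function(msg) stop_pulsebp(msg, "pulsebp_invalid_argument")
stop_insufficient <- function(msg) stop_pulsebp(msg, "pulsebp_insufficient_signal")
stop_degenerate <- function(msg) stop_pulsebp(msg, "pulsebp_degenerate_input")
stop_empty <- function(msg) stop_pulsebp(msg, "pulsebp_empty_result")
stop_schema <- function(msg) stop_pulsebp(msg, "pulsebp_schema_error")
stop_illcond <- function(msg) stop_pulsebp(msg, "pulsebp_ill_conditioned")
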