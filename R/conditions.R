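# Classed conditions so callers (and the command-line front-end) can map
# failure modes to exit codes: validation errors vs degenerate statistics.

stop_validation <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("cotrend_validation_error", "cotrend_error")))
}

stop_degenerate <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("cotrend_degenerate_error", "cotrend_error")))
}

stop_incomplete_set <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("cotrend_incomplete_set", "cotrend_error")))
}

stop_empty_result <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("cotrend_empty_result",
                                "cotrend_degenerate_error", "cotrend_error")))
}
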