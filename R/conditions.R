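# Classed conditions so callers can distinguish bad inputs from degenerate
# geometry without matching on message text.

stop_invalid <- function(msg, call. = FALSE) {
  stop(errorCondition(msg, class = c("retinotort_invalid_input", "error", "condition")))
}

stop_degenerate <- function(msg) {
  stop(errorCondition(msg, class = c("retinotort_degenerate", "error", "condition")))
}

stop_empty_tree <- function(msg = "vessel tree contains no measurable segments") {
  stop(errorCondition(msg, class = c("retinotort_empty_tree", "error", "condition")))
}

stop_layout <- function(msg) {
  stop(errorCondition(msg, class = c("retinotort_layout_failure", "error", "condition")))
}
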