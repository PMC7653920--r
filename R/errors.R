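# Classed conditions so callers (and tests) can distinguish failure modes:
#   scte_format_error    - a file does not parse as the declared format
#   scte_integrity_error - parsed data violate a container invariant
#   scte_config_error    - invalid user-supplied parameter
#   scte_input_error     - arguments inconsistent with the data
#   scte_undefined_error - statistic undefined for the given input
scte_error <- function(message, class) {
  stop(errorCondition(message, class = c(class, "scte_error")))
}

format_error    <- function(msg) scte_error(msg, "scte_format_error")
integrity_error <- function(msg) scte_error(msg, "scte_integrity_error")
config_error    <- function(msg) scte_error(msg, "scte_config_error")
input_error     <- function(msg) scte_error(msg, "scte_input_error")
undefined_error <- function(msg) scte_error(msg, "scte_undefined_error")
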