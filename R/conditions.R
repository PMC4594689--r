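# Classed conditions so callers (and the analysis drivers) can distinguish
# bad input from a computation that cannot proceed.

stop_validation <- function(msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c("il2rameta_validation_error", "il2rameta_error"),
                      call = call))
}

stop_computation <- function(msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c("il2rameta_computation_error", "il2rameta_error"),
                      call = call))
}
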