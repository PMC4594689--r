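# Shared by the numbered analysis drivers: run a step with distinct exit
# codes for bad input (2) vs a computation that cannot proceed (3).

run_step <- function(expr) {
  tryCatch(expr,
    il2rameta_validation_error = function(e) {
      message("input error: ", conditionMessage(e)); quit(status = 2L)
    },
    il2rameta_computation_error = function(e) {
      message("computation error: ", conditionMessage(e)); quit(status = 3L)
    },
    error = function(e) {
      message("error: ", conditionMessage(e)); quit(status = 1L)
    })
}

fmt_or <- function(res) sprintf("%.2f (%.2f-%.2f)", res$pooled_or, res$ci_low, res$ci_high)
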