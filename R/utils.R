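# Internal condition helpers. Three condition classes map onto the CLI's
# exit codes: config (bad options), data (bad input files/values),
# internal (contract violations inside the pipeline).

ckd_stop <- function(msg, class = "ckd_internal_error", call. = FALSE) {
  stop(structure(
    class = c(class, "ckd_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}

ckd_config_error <- function(msg) ckd_stop(msg, "ckd_config_error")
ckd_data_error <- function(msg) ckd_stop(msg, "ckd_data_error")
ckd_invalid_input <- function(msg) ckd_stop(msg, "ckd_invalid_input_error")
ckd_contract_violation <- function(msg) ckd_stop(msg, "ckd_contract_error")

assert_sorted <- function(x, what = "series") {
  if (is.unsorted(x, na.rm = FALSE))
    ckd_contract_violation(sprintf("%s must be sorted by time", what))
  invisible(x)
}

#' Days in one year used for slope/age arithmetic
#' @keywords internal
DAYS_PER_YEAR <- 365.25
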