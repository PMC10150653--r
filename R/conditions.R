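# Classed error conditions used across the package so callers (and the CLI)
# can distinguish configuration problems from data problems.

abort_emt <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "emtstrat_error", "error", "condition")))
}

format_error        <- function(msg) abort_emt(msg, "emtstrat_format_error")
duplicate_id_error  <- function(msg) abort_emt(msg, "emtstrat_duplicate_id_error")
validation_error    <- function(msg) abort_emt(msg, "emtstrat_validation_error")
missing_gene_error  <- function(msg) abort_emt(msg, "emtstrat_missing_gene_error")
config_error        <- function(msg) abort_emt(msg, "emtstrat_config_error")
input_error         <- function(msg) abort_emt(msg, "emtstrat_input_error")
insufficient_data_error <- function(msg) abort_emt(msg, "emtstrat_insufficient_data_error")
degenerate_data_error   <- function(msg) abort_emt(msg, "emtstrat_degenerate_data_error")
undefined_correlation_error <- function(msg) abort_emt(msg, "emtstrat_undefined_correlation_error")
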