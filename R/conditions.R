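# Typed error conditions. Every validation failure raises a classed condition so
# callers (and tests) can distinguish schema problems from integrity or QC
# problems without parsing message strings.

ngr_abort <- function(message, class, ..., call = NULL) {
  stop(structure(
    class = c(class, "ngr_error", "error", "condition"),
    list(message = message, call = call, ...)
  ))
}

abort_schema    <- function(msg, ...) ngr_abort(msg, "ngr_schema_error", ...)
abort_integrity <- function(msg, ...) ngr_abort(msg, "ngr_integrity_error", ...)
abort_value     <- function(msg, ...) ngr_abort(msg, "ngr_value_error", ...)
abort_validation<- function(msg, ...) ngr_abort(msg, "ngr_validation_error", ...)
abort_qc        <- function(msg, ...) ngr_abort(msg, "ngr_qc_error", ...)
abort_config    <- function(msg, ...) ngr_abort(msg, "ngr_config_error", ...)
abort_io        <- function(msg, ...) ngr_abort(msg, "ngr_io_error", ...)
abort_data      <- function(msg, ...) ngr_abort(msg, "ngr_data_error", ...)
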