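# Condition classes used throughout the conversion pipeline.
#
#   fw_usage_error     bad run configuration (unknown checklist, bad flag,
#                      unsupported file extension)           -> exit code 1
#   fw_parse_error     the input flat file cannot be parsed  -> exit code 2
#   fw_coherence_error marker abbreviations contradict the selected
#                      checklist type; aborts the whole run  -> exit code 3
#   fw_record_error    one record cannot be processed; the record is
#                      skipped, the run continues
#   fw_output_error    output file exists and --force not given

fw_stop <- function(class, msg) {
  stop(structure(
    class = c(class, "fw_error", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

stop_usage     <- function(msg) fw_stop("fw_usage_error", msg)
stop_parse     <- function(msg) fw_stop("fw_parse_error", msg)
stop_record    <- function(msg) fw_stop("fw_record_error", msg)
stop_coherence <- function(msg) fw_stop("fw_coherence_error", msg)
stop_output    <- function(msg) fw_stop("fw_output_error", msg)
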