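# Condition classes used across the package; the CLI maps them to exit codes
# (usage -> 1, format/data -> 2).

stop_format <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("cclid_format_error", "cclid_error", "error")))
}

stop_data <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("cclid_data_error", "cclid_error", "error")))
}

stop_usage <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("cclid_usage_error", "cclid_error", "error")))
}
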