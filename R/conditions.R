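## Classed conditions used across the package so callers (and tests) can
## distinguish format, integrity, lookup, configuration and argument failures.

stop_cmkg <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "cmkg_error"), call = call))
}

format_error    <- function(msg) stop_cmkg(msg, "cmkg_format_error")
integrity_error <- function(msg) stop_cmkg(msg, "cmkg_integrity_error")
lookup_error    <- function(msg) stop_cmkg(msg, "cmkg_lookup_error")
config_error    <- function(msg) stop_cmkg(msg, "cmkg_config_error")
argument_error  <- function(msg) stop_cmkg(msg, "cmkg_argument_error")
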