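# Classed conditions so callers (and the CLI) can tell contract violations
# (exit 2) from processing failures (exit 1).

stop_arg <- function(...) {
  stop(errorCondition(paste0(...), class = c("bs_arg_error", "bs_error")))
}

stop_format <- function(...) {
  stop(errorCondition(paste0(...), class = c("bs_format_error", "bs_error")))
}

stop_shape <- function(...) {
  stop(errorCondition(paste0(...), class = c("bs_shape_error", "bs_error")))
}

stop_io <- function(...) {
  stop(errorCondition(paste0(...), class = c("bs_io_error", "bs_error")))
}
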