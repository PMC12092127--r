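## Classed conditions so callers (and the CLI) can distinguish bad
## configuration from bad data rows from internal stage failures.

hr_stop <- function(msg, class, ...) {
  stop(errorCondition(msg, ..., class = c(class, "hadalrange_error")))
}

stop_config <- function(msg, ...) hr_stop(msg, "hadalrange_config_error", ...)

stop_validation <- function(msg, rows = NULL, ...) {
  if (!is.null(rows)) {
    msg <- sprintf("%s [rows: %s]", msg, paste(rows, collapse = ", "))
  }
  hr_stop(msg, "hadalrange_validation_error", rows = rows, ...)
}

warn_flag <- function(msg, class = "hadalrange_warning") {
  warning(warningCondition(msg, class = c(class, "hadalrange_warning")))
  invisible(NULL)
}
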