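# Internal helpers: classed conditions and small validators.

sdc_abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "sdc_error", "error", "condition")))
}

stop_parameter <- function(msg) sdc_abort(msg, "sdc_parameter_error")
stop_schema <- function(msg) sdc_abort(msg, "sdc_schema_error")
stop_input <- function(msg) sdc_abort(msg, "sdc_input_error")

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)
}

check_count <- function(x, name, min = 0) {
  if (!is_count(x) || x < min) {
    stop_parameter(sprintf("'%s' must be an integer >= %d, got %s",
                           name, min, deparse(substitute(x))))
  }
  as.integer(x)
}

check_number <- function(x, name, min = -Inf, strict = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    if (strict) x > min else x >= min
  if (!ok) stop_parameter(sprintf("'%s' must be a finite number %s %s",
                                  name, if (strict) ">" else ">=", format(min)))
  as.numeric(x)
}
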