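# Internal validation helpers shared across modules.

abort_domain <- function(msg) rlang::abort(msg, class = "quantneuron_domain_error")
abort_numeric <- function(msg) rlang::abort(msg, class = "quantneuron_numeric_error")
abort_config <- function(msg) rlang::abort(msg, class = "quantneuron_config_error")

check_finite <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    abort_domain(sprintf("`%s` must be finite and numeric.", name))
  }
  invisible(x)
}

check_scalar <- function(x, name) {
  if (length(x) != 1L) abort_domain(sprintf("`%s` must be a single value.", name))
  check_finite(x, name)
}

check_positive <- function(x, name) {
  check_scalar(x, name)
  if (x <= 0) abort_domain(sprintf("`%s` must be > 0.", name))
  invisible(x)
}

check_nonnegative <- function(x, name) {
  check_scalar(x, name)
  if (x < 0) abort_domain(sprintf("`%s` must be >= 0.", name))
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  check_scalar(x, name)
  if (x < min || x != round(x)) {
    abort_domain(sprintf("`%s` must be an integer >= %d.", name, min))
  }
  invisible(as.integer(x))
}
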