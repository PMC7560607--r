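# Internal argument checks. Every error names the offending field so that
# misconfigured simulations fail loudly at construction, not mid-pipeline.

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_scalar_num <- function(x, field, positive = FALSE, nonneg = FALSE,
                             integer = FALSE, min = NULL, max = NULL) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop_field(field, "must be a single non-missing number")
  }
  if (integer && x != trunc(x)) stop_field(field, "must be an integer")
  if (positive && x <= 0) stop_field(field, "must be > 0")
  if (nonneg && x < 0) stop_field(field, "must be >= 0")
  if (!is.null(min) && x < min) stop_field(field, paste("must be >=", min))
  if (!is.null(max) && x > max) stop_field(field, paste("must be <=", max))
  invisible(x)
}

check_prob <- function(x, field) {
  check_scalar_num(x, field, min = 0, max = 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
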