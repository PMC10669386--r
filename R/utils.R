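# Internal input validators shared across modules.

stop_invalid <- function(field, msg) {
  stop(sprintf("invalid input `%s`: %s", field, msg), call. = FALSE)
}

check_glucose <- function(x, field, max_value = 1000) {
  if (!is.numeric(x) || length(x) == 0) {
    stop_invalid(field, "must be numeric and non-empty")
  }
  if (any(!is.finite(x))) stop_invalid(field, "must be finite")
  if (any(x <= 0)) stop_invalid(field, "must be > 0 mg/dL")
  if (any(x > max_value)) {
    stop_invalid(field, sprintf("exceeds sanity bound %g mg/dL", max_value))
  }
  invisible(x)
}

check_scalar <- function(x, field, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    stop_invalid(field, "must be a single finite number")
  }
  if (strict && x <= lower) stop_invalid(field, sprintf("must be > %g", lower))
  if (!strict && x < lower) stop_invalid(field, sprintf("must be >= %g", lower))
  invisible(x)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
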