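
abort_value <- function(msg, ...) abort(msg, class = "jaenet_error_value", ...)
abort_format <- function(msg, ...) abort(msg, class = "jaenet_error_format", ...)
abort_insufficient <- function(msg, ...) abort(msg, class = "jaenet_error_insufficient_data", ...)
abort_degenerate <- function(msg, ...) abort(msg, class = "jaenet_error_degenerate", ...)
abort_design <- function(msg, ...) abort(msg, class = "jaenet_error_design", ...)

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is_scalar_number(x) || x < lower || x > upper) {
    abort_value(sprintf("`%s` must be a single finite number in [%s, %s].",
                        name, format(lower), format(upper)))
  }
  invisible(x)
}

# Derive a stream of child seeds from one master seed, each < 2^31.
derive_seeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}
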