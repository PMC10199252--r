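# Internal helpers: deterministic seed derivation and typed error conditions.

#' Derive a child seed from a master seed and a counter path
#'
#' Deterministic counter-based mixing so that every repetition / fold /
#' bootstrap draws from its own reproducible stream. Keeps results identical
#' across runs and independent of evaluation order.
#'
#' @param seed integer master seed.
#' @param ... integer counters identifying the consumer (e.g. repetition,
#'   fold index).
#' @return a single integer in `[1, 2^31 - 2]`.
#' @keywords internal
child_seed <- function(seed, ...) {
  m <- 2147483647 # 2^31 - 1, Mersenne prime used by classic Lehmer generators
  s <- as.double(seed %% m)
  for (k in c(...)) {
    s <- (s * 69069 + (as.double(k) + 1) * 30011) %% m
    s <- (s * 40692) %% m
  }
  as.integer(s %% (m - 2L)) + 1L
}

# run code under a local RNG seed without touching the caller's RNG state
with_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}

stop_modulearn <- function(msg, class, ...) {
  abort(msg, class = c(class, "modulearn_error"), ...)
}

# condition classes used across modules (kept few and predictable):
#   modulearn_format_error     - malformed file / missing mandatory column
#   modulearn_parse_error      - unreadable cell value
#   modulearn_validation_error - content inconsistent with panel/design
#   modulearn_contract_error   - caller broke an interface precondition
#   modulearn_data_error       - degenerate or insufficient data
#   modulearn_parameter_error  - invalid numeric configuration

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

`%.%` <- function(a, b) paste0(a, b)
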