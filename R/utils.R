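#' @keywords internal
"_PACKAGE"

#' Round half away from zero at a fixed number of decimals
#'
#' Percentages in the clinical-utility panels are printed with conventional
#' "half-up" rounding (0.05 -> 0.1), not the IEEE round-half-even used by
#' [base::round()].
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded half-up to `digits` decimals.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# Derive a stream-specific child seed from a base seed. Keeps all child
# seeds inside 32-bit integer range.
derive_seed <- function(seed, stream) {
  (as.double(seed) * 7919 + as.double(stream) * 104729) %% 2147483629 + 1
}

# Evaluate `expr` with a temporarily seeded RNG, restoring global state.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_that <- function(ok, fmt, ...) {
  if (!isTRUE(ok)) stopf(fmt, ...)
  invisible(TRUE)
}
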