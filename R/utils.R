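# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a child seed from a master seed
#'
#' Deterministic mixing of a master seed with a stream offset, kept strictly
#' below 2^31 so the result is always a valid R integer seed.
#'
#' @param seed integer master seed.
#' @param offset non-negative integer stream identifier.
#' @return a single integer seed.
#' @keywords internal
deriveSeed <- function(seed, offset = 0L) {
  s <- (as.double(seed) %% 2147483647) + 1
  as.integer((s * 48271 + as.double(offset) * 1299721) %% 2147483647)
}

assertScalarNumber <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper)
    stop(sprintf("'%s' must be a single finite number in [%s, %s]", name, lower, upper),
         call. = FALSE)
  invisible(x)
}

txMessage <- function(..., verbose = getOption("txatlas.verbose", FALSE)) {
  if (isTRUE(verbose)) message(...)
  invisible(NULL)
}
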