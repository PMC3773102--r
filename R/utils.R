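#' Round half away from zero
#'
#' Display rounding used throughout report output: ties are rounded away from
#' zero (0.0485 -> 0.049), unlike [base::round()]'s banker's rounding. Matches
#' the convention of the printed per-locus diversity tables this package
#' mirrors.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded to `digits` decimals.
#' @export
round_half_away <- function(x, digits = 3) {
  f <- 10^digits
  # nudge by half an ulp-scale epsilon so values that are exact halves in
  # decimal but sit just below .5 in binary still round away from zero
  sign(x) * floor(abs(x) * f + 0.5 + sqrt(.Machine$double.eps)) / f
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' @keywords internal
is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

# sample() without its length-1 surprise
sample_safe <- function(x, size, replace = FALSE, prob = NULL) {
  x[sample.int(length(x), size, replace = replace, prob = prob)]
}
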