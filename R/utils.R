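## internal helpers

## round half away from zero (base round() is banker's rounding)
roundHalfUp <- function(x) floor(x + 0.5)

## overflow-safe hyperbolic secant: cosh overflows past ~710
sech <- function(x) {
  ax <- abs(x)
  out <- numeric(length(x))
  big <- ax > 700
  out[big] <- 2 * exp(-ax[big])
  out[!big] <- 1 / cosh(ax[!big])
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## exact octave index under the half-open dialect: R >= 1 holds
## abundances in (2^(R-1), 2^R], with the singleton class {1, 2} at R = 1
halfopenOctave <- function(r) {
  pmax(1L, as.integer(ceiling(log2(r) - 1e-12)))
}

isPowerOfTwo <- function(r) bitwAnd(r, r - 1L) == 0L

stopfNamed <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
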