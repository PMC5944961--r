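## inverse CDF of the hyperbolic-secant location/rate family with density
## proportional to sech(alpha (x - Rm)): F(x) = (2/pi) atan(exp(alpha (x - Rm)))
## so F^-1(u) = Rm + log(tan(pi u / 2)) / alpha (derived analytically;
## unit-tested against rejection sampling)
qsech <- function(u, Rm, alpha) Rm + log(tan(pi * u / 2)) / alpha

## inverse CDF of the linear relative-abundance density f(r) = 2 - 2 r on
## [0, 1]: F(r) = 2 r - r^2, F^-1(u) = 1 - sqrt(1 - u)
qlinearON <- function(u) 1 - sqrt(1 - u)

## logseries abundance density on [1, Inf): f(r) = alpha^r / (r Gamma(0, -ln a)).
## The CDF is closed-form through the exponential integral E1:
## F(r) = 1 - E1(-r ln alpha) / E1(-ln alpha); inverted on a log-spaced
## knot table with monotone interpolation, resampling the far tail.
lserQuantileTable <- function(alpha, rMax = 1e6, knots = 4096L) {
  r <- exp(seq(log(1), log(rMax), length.out = knots))
  u <- 1 - pracma::expint_E1(-r * log(alpha)) / pracma::expint_E1(-log(alpha))
  keep <- !duplicated(u)
  list(r = r[keep], u = u[keep], uMax = max(u[keep]))
}

#' Generate a synthetic community from a SAD model's generative form
#'
#' Draws a hollow-curve community (many rare, few common species) whose
#' statistical structure matches one of the seven SAD models:
#' \describe{
#'   \item{GS}{rank proportions \eqn{p_j = k (1-k)^{j-1}} (niche
#'     preemption); abundance = round(N p_j). Needs `k` in (0,1) and `N`.}
#'   \item{BS}{broken-stick rank proportions
#'     \eqn{p_j = \frac{1}{S}\sum_{i=j}^{S} 1/i}; abundance = round(N p_j).
#'     Needs `N`.}
#'   \item{ON}{per-species relative abundance drawn from the linear
#'     density \eqn{f(r) = 2 - 2r} on [0, 1] by inverse CDF
#'     (\eqn{r = 1 - \sqrt{1-u}}), normalised across species and scaled to
#'     `N` before rounding. Needs `N`.}
#'   \item{LSer}{per-species abundance drawn from the logseries density
#'     \eqn{f(r) = \alpha^r / [r\, \Gamma(0, -\ln\alpha)]} on
#'     \eqn{[1, \infty)} by numeric inverse CDF. Needs `alpha` in (0,1).}
#'   \item{LN / LC / LS}{per-species octave value drawn from the
#'     normal(\eqn{R_m}, sd \eqn{1/(\alpha\sqrt2)}) / Cauchy(\eqn{R_m},
#'     scale \eqn{1/\alpha}) / hyperbolic-secant(location \eqn{R_m}, rate
#'     \eqn{\alpha}) law matching the model's octave-scale shape, then
#'     converted to an integer abundance \eqn{r = round(2^R)}. Need
#'     `alpha` and `R_m`.}
#' }
#' With `truncateAtOne = TRUE` (the veil line, default) species landing at
#' abundance below 1 are resampled; otherwise zero-abundance species are
#' dropped and the drop count reported in the `"dropped"` attribute.
#' Deterministic rank-proportion models round half-up and drop
#' zero-abundance ranks (reported); `multinomial = TRUE` instead samples
#' the `N` individuals multinomially over the rank proportions for
#' stochastic GS/BS/ON communities.
#'
#' @param model model name (any of the seven).
#' @param S number of species to generate (>= 3).
#' @param k preemption fraction in (0, 1) (GS only).
#' @param alpha shape constant (LSer in (0,1); LN/LC/LS > 0).
#' @param R_m modal octave (LN/LC/LS only).
#' @param N target total individuals (GS/BS/ON only).
#' @param seed mandatory integer seed.
#' @param truncateAtOne resample species below the veil line (LSer/LN/LC/LS
#'   and stochastic samplers).
#' @param multinomial sample individuals multinomially for GS/BS/ON.
#' @param community,layer labels for the generated dataset.
#' @return a [LayerDataset-class]; attribute `"dropped"` counts
#'   zero-abundance species removed when not truncating.
#' @examples
#' abundances(simulateCommunity("GS", S = 4, k = 0.5, N = 160, seed = 1))
#' abundances(simulateCommunity("BS", S = 3, N = 18, seed = 1))
#' @export
simulateCommunity <- function(model, S, k = NULL, alpha = NULL, R_m = NULL,
                              N = NULL, seed, truncateAtOne = TRUE,
                              multinomial = FALSE,
                              community = "synthetic", layer = NULL) {
  name <- normalizeModelName(model)
  stopifnot(S >= 3)
  if (missing(seed)) stopfNamed("a seed is mandatory for reproducibility")
  set.seed(as.integer(seed))

  dropped <- 0L
  if (name %in% c("GS", "BS", "ON")) {
    if (is.null(N)) stopfNamed("%s generator needs a target total N", name)
    p <- switch(name,
      GS = {
        if (is.null(k) || k <= 0 || k >= 1)
          stopfNamed("GS generator needs preemption fraction k in (0, 1)")
        k * (1 - k) ^ (seq_len(S) - 1)
      },
      BS = rev(cumsum(1 / rev(seq_len(S)))) / S,
      ON = {
        seg <- qlinearON(stats::runif(S))
        seg / sum(seg)
      })
    ab <- if (multinomial) as.numeric(stats::rmultinom(1L, size = N, prob = p))
          else roundHalfUp(N * p)
    dropped <- sum(ab < 1)
    ab <- ab[ab >= 1]
  } else if (name == "LSer") {
    if (is.null(alpha) || alpha <= 0 || alpha >= 1)
      stopfNamed("LSer generator needs alpha in (0, 1)")
    tab <- lserQuantileTable(alpha)
    draw <- function(m) {
      u <- stats::runif(m)
      out <- numeric(m)
      inTable <- u <= tab$uMax
      out[inTable] <- exp(stats::approx(tab$u, log(tab$r),
                                        xout = u[inTable], rule = 2)$y)
      nTail <- sum(!inTable)  # beyond the table: resample
      if (nTail) out[!inTable] <- draw(nTail)
      out
    }
    ab <- roundHalfUp(draw(S))
    ab[ab < 1] <- 1  # continuous draws start at r = 1
  } else {
    if (is.null(alpha) || alpha <= 0)
      stopfNamed("%s generator needs alpha > 0", name)
    if (is.null(R_m)) stopfNamed("%s generator needs a modal octave R_m", name)
    drawR <- switch(name,
      LN = function(m) stats::rnorm(m, R_m, 1 / (alpha * sqrt(2))),
      LC = function(m) stats::rcauchy(m, R_m, 1 / alpha),
      LS = function(m) qsech(stats::runif(m), R_m, alpha))
    ## abundances are integer counts: draws beyond the representable count
    ## range (heavy Cauchy right tail) are resampled, as are draws below
    ## the veil line when truncating
    maxAb <- .Machine$integer.max - 1
    ab <- roundHalfUp(2 ^ drawR(S))
    for (iter in seq_len(1000L)) {
      bad <- ab > maxAb | (if (truncateAtOne) ab < 1 else FALSE)
      if (!any(bad)) break
      ab[bad] <- roundHalfUp(2 ^ drawR(sum(bad)))
    }
    if (any(ab > maxAb) || (truncateAtOne && any(ab < 1)))
      stopfNamed("abundance resampling failed to converge")
    if (!truncateAtOne) {
      dropped <- sum(ab < 1)
      ab <- ab[ab >= 1]
    }
  }

  if (length(ab) < 3L)
    stopfNamed("generation produced fewer than 3 surviving species")
  ds <- layerDataset(sprintf("sp%04d", seq_along(ab)), as.integer(ab),
                     community = community,
                     layer = layer %||% tolower(name))
  attr(ds, "dropped") <- as.integer(dropped)
  ds
}

#' Noiseless expected histogram of a model
#'
#' Evaluates a model at the given octaves and wraps the values as an
#' [OctaveHistogram-class], giving an exact fixed point for [fitModel()]
#' (fitting the generating model to it recovers the parameters with zero
#' residual). Used throughout as a noiseless fixture.
#'
#' @param model model name or [SADModel-class].
#' @param params named parameter vector.
#' @param octaves integer octave values to evaluate at.
#' @param dataConstants `N_oct` and `R_max` for the ON model.
#' @return an [OctaveHistogram-class].
#' @examples
#' expectedHistogram("LC", c(S_m = 12, alpha = 0.8, R_m = 1), 1:8)
#' @export
expectedHistogram <- function(model, params, octaves, dataConstants = NULL) {
  vals <- evaluateModel(model, params, octaves,
                        dataConstants = dataConstants)
  octaveHistogram(octaves, vals,
                  label = paste0("expected ",
                                 normalizeModelName(
                                   if (is(model, "SADModel")) model@name
                                   else model)))
}
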