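#' Adjusted coefficient of determination of a nonlinear regression
#'
#' \deqn{R_d^2 = 1 - \frac{SS_{res}/(n-k)}{SS_{tot}/(n-1)}}
#' with \eqn{SS_{tot}} taken about the mean of the observed counts. The
#' statistic may be negative for a model fitting worse than the mean, and
#' is exactly zero for the one-parameter constant (geometric series) model,
#' whose least-squares solution is the mean itself. Setting
#' `adjusted = FALSE` gives the plain \eqn{R^2 = 1 - SS_{res}/SS_{tot}}.
#'
#' @param observed,fitted equal-length vectors of observed and fitted
#'   species counts per octave.
#' @param k number of free model parameters.
#' @param adjusted use the adjusted formula (default) or plain R^2.
#' @return the coefficient of determination (\eqn{\le 1}).
#' @examples
#' adjustedRSquared(c(3, 1, 1), c(3, 1, 1), k = 3)      # 1
#' adjustedRSquared(c(4, 2, 1), c(1, 2, 4), k = 2)      # -6.714...
#' @export
adjustedRSquared <- function(observed, fitted, k, adjusted = TRUE) {
  n <- length(observed)
  if (length(fitted) != n)
    stopfNamed("observed and fitted must have equal length")
  SStot <- sum((observed - mean(observed)) ^ 2)
  if (SStot == 0)
    stopfNamed("R^2 undefined: observed counts have zero variance")
  SSres <- sum((observed - fitted) ^ 2)
  if (!adjusted) return(1 - SSres / SStot)
  if (n <= k)
    stopfNamed("adjusted R^2 undefined for n = %d octaves and k = %d", n, k)
  1 - (SSres / (n - k)) / (SStot / (n - 1))
}

#' Chi-square goodness-of-fit test for an octave histogram
#'
#' Pearson's statistic \eqn{\chi^2 = \sum (S_{obs} - S_{fit})^2 / S_{fit}}
#' over the (pooled) octave classes, compared against the upper tail of the
#' \eqn{\chi^2} distribution. Classes whose fitted count falls below
#' `poolFloor` (the classical expected-count floor, default 1) are pooled
#' with their inner neighbour before the statistic is computed: an edge
#' class merges inward, an interior class merges toward the neighbour with
#' the larger fitted count. Degrees of freedom are the pooled class count
#' minus `k` (`dfConvention = "n-k"`, default) or minus `k + 1`; when fewer
#' than one degree of freedom remains the tail probability is undefined and
#' reported as `NA`.
#'
#' @param observed,fitted observed and fitted species counts per octave.
#' @param k number of free model parameters.
#' @param pooling pool low-expectation classes (default TRUE).
#' @param poolFloor expected-count floor below which classes are pooled.
#' @param dfConvention `"n-k"` or `"n-k-1"`.
#' @return a list with `chi2`, `df`, `P` and `nPooled` (the class count
#'   after pooling).
#' @examples
#' chiSquareGof(c(10, 5), c(8, 7), k = 1)   # chi2 = 1.0714, P = 0.3006
#' @export
chiSquareGof <- function(observed, fitted, k, pooling = TRUE, poolFloor = 1,
                         dfConvention = c("n-k", "n-k-1")) {
  dfConvention <- match.arg(dfConvention)
  if (length(observed) != length(fitted))
    stopfNamed("observed and fitted must have equal length")
  obs <- observed; fit <- fitted
  if (pooling) {
    while (length(fit) > 1L && any(fit < poolFloor)) {
      i <- which.min(fit)
      j <- if (i == 1L) 2L
           else if (i == length(fit)) i - 1L
           else if (fit[i + 1L] >= fit[i - 1L]) i + 1L else i - 1L
      fit[j] <- fit[j] + fit[i]
      obs[j] <- obs[j] + obs[i]
      fit <- fit[-i]; obs <- obs[-i]
    }
  }
  if (all(fit < poolFloor) || any(fit <= 0))
    stopfNamed("chi-square test not applicable: fitted counts below floor")
  chi2 <- sum((obs - fit) ^ 2 / fit)
  df <- length(fit) - k - if (dfConvention == "n-k-1") 1L else 0L
  P <- if (df >= 1) stats::pchisq(chi2, df, lower.tail = FALSE) else NA_real_
  list(chi2 = chi2, df = df, P = P, nPooled = length(fit))
}

#' Information criteria for a least-squares fit
#'
#' For a least-squares regression on \eqn{n} octaves with \eqn{k}
#' parameters and residual sum of squares \eqn{SS},
#' \deqn{AIC = n \ln(SS) + 2k - n \ln(n), \qquad
#'       BIC = n \ln(SS) + k \ln(n) - n \ln(n),}
#' so that \eqn{AIC - BIC = k (2 - \ln n)} identically. The lower the
#' criterion, the better the model. A perfect fit (\eqn{SS = 0}) returns
#' the `-Inf` sentinel for both.
#'
#' @param SS residual sum of squares.
#' @param n number of octaves (sample size).
#' @param k number of free parameters.
#' @return named numeric vector `c(AIC = , BIC = )`.
#' @examples
#' informationCriteria(SS = 1, n = 8, k = 3)
#' @export
informationCriteria <- function(SS, n, k) {
  if (SS < 0) stopfNamed("SS must be non-negative")
  if (SS == 0) return(c(AIC = -Inf, BIC = -Inf))
  base <- n * log(SS) - n * log(n)
  c(AIC = base + 2 * k, BIC = base + k * log(n))
}
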