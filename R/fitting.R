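#' Options controlling model fitting and adequacy assessment
#'
#' Collects the numerical and statistical conventions of the fitting stage.
#' Defaults follow the package's documented reproduction settings: adjusted
#' R^2, chi-square adequacy at the 0.05 level with expected-count pooling
#' and `df = n - k`, a 0.50 R_d^2 adequacy threshold, and a fixed
#' deterministic multistart (no randomness anywhere in fitting).
#'
#' @param maxIterations Levenberg-Marquardt iteration cap (clamped to the
#'   solver's 1024 maximum).
#' @param tolerance relative tolerance on the least-squares cost.
#' @param alphaLevel significance level of the chi-square adequacy test.
#' @param r2Threshold adequacy threshold on R_d^2.
#' @param dfConvention chi-square degrees of freedom, `"n-k"` or `"n-k-1"`.
#' @param pooling pool chi-square classes with fitted count below
#'   `poolFloor`.
#' @param poolFloor expected-count floor for pooling.
#' @param adjusted use adjusted R^2 (`FALSE` gives plain R^2).
#' @param alphaStarts multistart values for the shape constant of the BS
#'   (as multipliers of 1/mean(2^R)) and of the LN/LC/LS models.
#' @param lserAlphaStarts multistart values for the logseries alpha,
#'   all in (0, 1).
#' @return a named list of options.
#' @export
fitOptions <- function(maxIterations = 2000, tolerance = 1e-10,
                       alphaLevel = 0.05, r2Threshold = 0.50,
                       dfConvention = c("n-k", "n-k-1"),
                       pooling = TRUE, poolFloor = 1, adjusted = TRUE,
                       alphaStarts = c(0.3, 1, 3),
                       lserAlphaStarts = c(0.2, 0.5, 0.8)) {
  stopifnot(tolerance > 0, alphaLevel > 0, alphaLevel < 1,
            all(lserAlphaStarts > 0), all(lserAlphaStarts < 1))
  list(maxIterations = maxIterations, tolerance = tolerance,
       alphaLevel = alphaLevel, r2Threshold = r2Threshold,
       dfConvention = match.arg(dfConvention),
       pooling = pooling, poolFloor = poolFloor, adjusted = adjusted,
       alphaStarts = alphaStarts, lserAlphaStarts = lserAlphaStarts)
}

## starting points for one model on one histogram: a list of named vectors
startingPoints <- function(spec, R, Sobs, opts) {
  Sm0 <- max(Sobs)
  switch(spec@name,
    GS = list(c(S_m = mean(Sobs))),
    ON = list(c(S_m = Sm0)),
    BS = {
      ## 1/mean(2^R) targets the bulk; 2^-R_mode aligns the BS peak
      ## (at 2^R = 1/alpha) with the modal octave
      a0 <- c(opts$alphaStarts / mean(2 ^ R), 2 ^ -R[which.max(Sobs)])
      lapply(a0, function(a) c(S_m = Sm0, alpha = a))
    },
    LSer = lapply(opts$lserAlphaStarts, function(a)
      c(S_m = Sm0, alpha = a)),
    lapply(opts$alphaStarts, function(a)
      c(S_m = Sm0, alpha = a, R_m = as.numeric(R[which.max(Sobs)]))))
}

## solver box constraints for one model on one histogram
fitBounds <- function(spec, R, Sobs) {
  lower <- c(S_m = 1e-8, alpha = 1e-6, R_m = min(R) - 2)
  upper <- c(S_m = 10 * max(Sobs), alpha = Inf, R_m = max(R) + 2)
  if (spec@name == "LSer") upper["alpha"] <- 1 - 1e-8
  list(lower = lower[spec@paramNames], upper = upper[spec@paramNames])
}

## least-squares estimation core; returns list(params, SS, converged, note)
estimateParameters <- function(spec, R, Sobs, dataConst, opts) {
  if (spec@name == "GS") {
    p <- c(S_m = mean(Sobs))
    return(list(params = p, converged = TRUE, note = ""))
  }
  if (spec@name == "ON") {
    ## linear in S_m: closed-form least squares with frozen data constants
    g <- (1 - 2 ^ R / dataConst[["N_oct"]]) * 2 ^ R
    if (sum(g ^ 2) == 0)
      stopfNamed("ON model degenerate: zero regressor on all octaves")
    p <- c(S_m = sum(g * Sobs) / sum(g ^ 2))
    return(list(params = p, converged = TRUE, note = ""))
  }
  bounds <- fitBounds(spec, R, Sobs)
  ctrl <- minpack.lm::nls.lm.control(
    ftol = opts$tolerance, ptol = 1e-12,
    maxiter = min(opts$maxIterations, 1024))
  resid <- function(par) {
    Sobs - evaluateModel(spec, stats::setNames(par, spec@paramNames), R,
                         dataConstants = dataConst)
  }
  best <- NULL
  for (start in startingPoints(spec, R, Sobs, opts)) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = start, lower = bounds$lower,
                         upper = bounds$upper, fn = resid, control = ctrl),
      error = function(e) NULL)
    if (is.null(fit)) next
    ss <- sum(fit$fvec ^ 2)
    ok <- fit$info %in% 1:3
    if (is.null(best) || ss < best$SS - 1e-15 ||
        (ss <= best$SS + 1e-15 && ok && !best$converged)) {
      best <- list(params = stats::setNames(fit$par, spec@paramNames),
                   SS = ss, converged = ok,
                   note = if (ok) "" else paste("solver:", fit$message))
    }
  }
  if (is.null(best))
    stopfNamed("all starting points failed for model %s", spec@name)
  best[c("params", "converged", "note")]
}

#' Fit one SAD model to an octave histogram
#'
#' Estimates the model's parameters by least squares on the regression of
#' the observed species count \eqn{S_{obs}(R)} against the octave \eqn{R},
#' then populates every goodness-of-fit statistic used for model selection.
#' The one-parameter constant (GS) and overlapping-niche (ON) models are
#' solved in closed form; the remaining models use bounded
#' Levenberg-Marquardt iteration from a fixed deterministic multistart
#' (curve height from the tallest octave, peak position from the modal
#' octave, several shape-constant starts), keeping the lowest residual sum
#' of squares. Fractional counts from the boundary-halving dialect enter
#' the sums of squares and the chi-square statistic as-is.
#'
#' If no start converges the best point found is still returned with
#' `converged = FALSE` and its statistics computed; fewer octaves than
#' parameters is an error.
#'
#' @param object a [SADModel-class] or model name.
#' @param histogram an [OctaveHistogram-class].
#' @param options a [fitOptions()] list.
#' @param ... unused.
#' @return a [SADFit-class].
#' @examples
#' h <- expectedHistogram("LC", c(S_m = 12, alpha = 0.8, R_m = 1), 1:8)
#' fitModel("LC", h)   # recovers (12, 0.8, 1) with SS ~ 0
#' @export
setMethod("fitModel", signature(object = "SADModel",
                                histogram = "OctaveHistogram"),
          function(object, histogram, options = fitOptions(), ...) {
  spec <- object
  R <- histogram@octave
  Sobs <- histogram@count
  n <- length(R)
  if (spec@name == "LSer" && any(R < 0))
    stopfNamed("LSer is defined only on octaves R >= 0 (histogram starts at %d)",
               min(R))
  if (n < spec@k)
    stopfNamed("insufficient data: %d octaves for %d parameters (%s)",
               n, spec@k, spec@name)
  dataConst <- c(N_oct = octaveTotal(histogram), R_max = max(R))

  est <- estimateParameters(spec, R, Sobs, dataConst, options)
  Sfit <- evaluateModel(spec, est$params, R, dataConstants = dataConst)
  SS <- sum((Sobs - Sfit) ^ 2)

  Rd2 <- tryCatch(
    adjustedRSquared(Sobs, Sfit, spec@k, adjusted = options$adjusted),
    error = function(e) NA_real_)
  gof <- tryCatch(
    chiSquareGof(Sobs, Sfit, spec@k, pooling = options$pooling,
                 poolFloor = options$poolFloor,
                 dfConvention = options$dfConvention),
    error = function(e) list(chi2 = NA_real_, df = NA_real_, P = NA_real_))
  ic <- informationCriteria(SS, n, spec@k)
  Sstar <- if (spec@hasSstar) sstarClosedForm(spec@name, est$params)
           else NA_real_

  new("SADFit", model = spec@name, params = est$params,
      dataConstants = dataConst, octave = R, observed = Sobs, fitted = Sfit,
      SS = SS, n = as.integer(n), k = spec@k,
      Rd2 = Rd2, chi2 = as.numeric(gof$chi2), df = as.numeric(gof$df),
      P = as.numeric(gof$P), AIC = unname(ic["AIC"]),
      BIC = unname(ic["BIC"]), Sstar = Sstar,
      converged = est$converged, note = est$note)
})

#' @rdname fitModel-SADModel-OctaveHistogram-method
#' @export
setMethod("fitModel", signature(object = "character",
                                histogram = "OctaveHistogram"),
          function(object, histogram, options = fitOptions(), ...) {
  fitModel(sadModel(object), histogram, options = options, ...)
})
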