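#' The seven SAD models on the octave scale
#'
#' All models express the expected number of species \eqn{S(R)} in octave
#' \eqn{R} (the log2 abundance class). Writing \eqn{S_m} for the curve
#' height, \eqn{\alpha} for the shape constant and \eqn{R_m} for the modal
#' octave, the functional forms are
#' \describe{
#'   \item{GS}{geometric series (niche preemption), constant on octaves:
#'     \eqn{S(R) = S_m}.}
#'   \item{BS}{broken stick (exponential on the arithmetic scale):
#'     \eqn{S(R) = S_m \exp(-\alpha 2^R + R \ln 2)}.}
#'   \item{ON}{overlapping niche (linear relative-abundance density):
#'     \eqn{S(R) = S_m (1 - 2^R / N_{oct}) 2^R}, with the
#'     octave-transformed total \eqn{N_{oct} = \sum 2^R S_{obs}(R)} and the
#'     largest observed octave frozen from the data (so k = 1).}
#'   \item{LSer}{Fisher's logseries: \eqn{S(R) = S_m \alpha^{2^R}},
#'     \eqn{0 < \alpha < 1}, defined for \eqn{R \ge 0}.}
#'   \item{LN}{lognormal: \eqn{S(R) = S_m \exp[-\alpha^2 (R - R_m)^2]}.}
#'   \item{LC}{logCauchy: \eqn{S(R) = S_m / [1 + \alpha^2 (R - R_m)^2]}.}
#'   \item{LS}{log-sech: \eqn{S(R) = S_m \,\mathrm{sech}[\alpha (R - R_m)]}.}
#' }
#'
#' `sadModels()` returns the full registry of seven [SADModel-class]
#' specifications in the fixed order GS, BS, ON, LSer, LN, LC, LS;
#' `sadModel(name)` returns a single one (names are case-insensitive, so
#' the lower-case forms `"gs", "bs", "on", "lser", "ln", "lc", "ls"` used
#' in configuration files are accepted).
#'
#' @param name model name, e.g. `"LC"` or `"lc"`.
#' @return `sadModels()`: a named list of seven [SADModel-class] objects;
#'   `sadModel()`: one [SADModel-class].
#' @examples
#' length(sadModels())
#' sadModel("lc")
#' @export
sadModels <- function() {
  mk <- function(name, paramNames, lower, upper, hasSstar, needsData = FALSE)
    new("SADModel", name = name, k = length(paramNames),
        paramNames = paramNames, lower = lower, upper = upper,
        hasSstar = hasSstar, needsDataConstants = needsData)
  list(
    GS   = mk("GS", "S_m", 0, Inf, hasSstar = FALSE),
    BS   = mk("BS", c("S_m", "alpha"), c(0, 1e-6), c(Inf, Inf),
              hasSstar = TRUE),
    ON   = mk("ON", "S_m", 0, Inf, hasSstar = TRUE, needsData = TRUE),
    LSer = mk("LSer", c("S_m", "alpha"), c(0, 1e-6), c(Inf, 1 - 1e-8),
              hasSstar = FALSE),
    LN   = mk("LN", c("S_m", "alpha", "R_m"), c(0, 1e-6, -Inf),
              c(Inf, Inf, Inf), hasSstar = TRUE),
    LC   = mk("LC", c("S_m", "alpha", "R_m"), c(0, 1e-6, -Inf),
              c(Inf, Inf, Inf), hasSstar = TRUE),
    LS   = mk("LS", c("S_m", "alpha", "R_m"), c(0, 1e-6, -Inf),
              c(Inf, Inf, Inf), hasSstar = TRUE))
}

#' @rdname sadModels
#' @export
sadModel <- function(name) {
  key <- normalizeModelName(name)
  sadModels()[[key]]
}

normalizeModelName <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  key <- c(gs = "GS", bs = "BS", on = "ON", lser = "LSer",
           ln = "LN", lc = "LC", ls = "LS")[tolower(name)]
  if (is.na(key)) stopfNamed("unknown SAD model '%s'", name)
  unname(key)
}

#' Evaluate a SAD model at given octaves
#'
#' Computes the expected species count \eqn{S(R)} of one model at the octave
#' values `R`, for the parameter vector `params` (named `S_m`, `alpha`,
#' `R_m` as required by the model; see [sadModels()] for the functional
#' forms). The overlapping-niche model additionally needs the data constants
#' `N_oct` and `R_max` frozen from the histogram, passed via
#' `dataConstants`, and is only defined where \eqn{2^R \le N_{oct}}.
#'
#' @param model a [SADModel-class] or a model name.
#' @param params named numeric vector of parameters.
#' @param R numeric vector of octave values.
#' @param dataConstants named vector with `N_oct` and `R_max` (ON only).
#' @return numeric vector of expected species counts, non-negative on the
#'   model's domain.
#' @examples
#' evaluateModel("LC", c(S_m = 10, alpha = 1, R_m = 2), R = 2:3) # 10, 5
#' @export
evaluateModel <- function(model, params, R, dataConstants = NULL) {
  spec <- if (is(model, "SADModel")) model else sadModel(model)
  need <- spec@paramNames
  if (!all(need %in% names(params)))
    stopfNamed("model %s needs parameters: %s", spec@name,
               paste(need, collapse = ", "))
  Sm <- unname(params["S_m"])
  switch(spec@name,
    GS = rep_len(Sm, length(R)),
    BS = Sm * exp(-unname(params["alpha"]) * 2 ^ R + R * log(2)),
    ON = {
      if (is.null(dataConstants) ||
          !all(c("N_oct", "R_max") %in% names(dataConstants)))
        stopfNamed("ON model needs dataConstants N_oct and R_max")
      Noct <- unname(dataConstants["N_oct"])
      if (any(2 ^ R > Noct * (1 + 1e-9)))
        stopfNamed("ON model undefined where 2^R exceeds N_oct = %g", Noct)
      Sm * (1 - 2 ^ R / Noct) * 2 ^ R
    },
    LSer = {
      if (any(R < 0))
        stopfNamed("LSer model is defined only for octaves R >= 0")
      Sm * unname(params["alpha"]) ^ (2 ^ R)
    },
    LN = Sm * exp(-unname(params["alpha"]) ^ 2 *
                    (R - unname(params["R_m"])) ^ 2),
    LC = Sm / (1 + unname(params["alpha"]) ^ 2 *
                 (R - unname(params["R_m"])) ^ 2),
    LS = Sm * sech(unname(params["alpha"]) * (R - unname(params["R_m"]))))
}

#' Extrapolated total species richness S*
#'
#' The expected total number of species in the whole community is estimated
#' as the area below the complete (untruncated) fitted octave curve —
#' extrapolating below the veil line. Closed forms:
#' \deqn{S^*_{BS} = S_m / (\alpha \ln 2), \quad
#'       S^*_{ON} = S_m / (2 \ln 2), \quad
#'       S^*_{LN} = \sqrt{\pi}\, S_m / \alpha, \quad
#'       S^*_{LC} = S^*_{LS} = \pi S_m / \alpha.}
#' The geometric series has no finite area and the logseries cannot
#' extrapolate total richness; both raise an error.
#'
#' @param object a [SADModel-class], model name, or [SADFit-class].
#' @param params named parameter vector (ignored for a SADFit, which uses
#'   its own estimates).
#' @param ... unused.
#' @return the S* estimate (species).
#' @examples
#' totalRichness("LC", c(S_m = 10, alpha = 0.5, R_m = 1)) # 20 * pi
#' @export
setMethod("totalRichness", "SADModel", function(object, params, ...) {
  sstarClosedForm(object@name, params)
})

#' @rdname totalRichness-SADModel-method
#' @export
setMethod("totalRichness", "character", function(object, params, ...) {
  sstarClosedForm(normalizeModelName(object), params)
})

#' @rdname totalRichness-SADModel-method
#' @export
setMethod("totalRichness", "SADFit", function(object, ...) {
  sstarClosedForm(object@model, object@params)
})

sstarClosedForm <- function(name, params) {
  Sm <- unname(params["S_m"])
  a <- unname(params["alpha"])
  switch(name,
    BS = Sm / (a * log(2)),
    ON = Sm / (2 * log(2)),
    LN = sqrt(pi) * Sm / a,
    LC = pi * Sm / a,
    LS = pi * Sm / a,
    stopfNamed("model %s cannot extrapolate total richness S*", name))
}
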