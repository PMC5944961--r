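modelOrder <- c("GS", "BS", "ON", "LSer", "LN", "LC", "LS")

#' Fit all seven SAD models to one histogram
#'
#' Runs [fitModel()] for every model in the fixed order GS, BS, ON, LSer,
#' LN, LC, LS and bundles the results into a [SADComparison-class].
#' Per-model failures (e.g. too few octaves for a three-parameter model)
#' never abort the table: the failing model gets a placeholder row with
#' `converged = FALSE`, `NA` statistics and the error message in its note.
#'
#' @param histogram an [OctaveHistogram-class].
#' @param options a [fitOptions()] list.
#' @param models model names to fit (default: all seven).
#' @return a [SADComparison-class].
#' @examples
#' h <- expectedHistogram("LC", c(S_m = 12, alpha = 0.8, R_m = 1), 1:8)
#' cmp <- fitAllModels(h)
#' selectBest(cmp, criterion = "aic")
#' @export
fitAllModels <- function(histogram, options = fitOptions(),
                         models = modelOrder) {
  models <- vapply(models, normalizeModelName, character(1L))
  models <- modelOrder[modelOrder %in% models]
  fits <- lapply(models, function(m) {
    tryCatch(fitModel(m, histogram, options = options),
             error = function(e) failedFit(m, histogram, conditionMessage(e)))
  })
  names(fits) <- models
  if (identical(models, modelOrder))
    new("SADComparison", label = histogram@label, fits = fits,
        options = options)
  else
    structure(list(label = histogram@label, fits = fits, options = options),
              class = "partialSADComparison")
}

## placeholder row for a model that could not be fitted
failedFit <- function(name, histogram, message) {
  spec <- sadModel(name)
  new("SADFit", model = spec@name,
      params = stats::setNames(rep(NA_real_, spec@k), spec@paramNames),
      dataConstants = c(N_oct = octaveTotal(histogram),
                        R_max = max(histogram@octave)),
      octave = histogram@octave, observed = histogram@count,
      fitted = rep(NA_real_, length(histogram@octave)),
      SS = NA_real_, n = length(histogram@octave), k = spec@k,
      Rd2 = NA_real_, chi2 = NA_real_, df = NA_real_, P = NA_real_,
      AIC = NA_real_, BIC = NA_real_, Sstar = NA_real_,
      converged = FALSE, note = message)
}

#' @rdname as.data.frame.SADFit
#' @method as.data.frame partialSADComparison
#' @export
as.data.frame.partialSADComparison <- function(x, row.names = NULL,
                                               optional = FALSE, ...) {
  out <- do.call(rbind, lapply(x$fits, as.data.frame))
  rownames(out) <- NULL
  out
}

#' Adequacy flags for each fitted model
#'
#' Two boolean criteria per model: `chi2Pass` — the chi-square tail
#' probability satisfies \eqn{P \ge} `alphaLevel` (the model statistically
#' agrees with the data); `r2Pass` — the coefficient of determination
#' satisfies \eqn{R_d^2 \ge} `r2Threshold`. An undefined P (degrees of
#' freedom below one, or the test not applicable) yields `NA` for
#' `chi2Pass`.
#'
#' @param object a [SADComparison-class].
#' @param options thresholds; defaults to the options stored in the table.
#' @param ... unused.
#' @return a data.frame with columns `model, chi2Pass, r2Pass`.
#' @export
setMethod("adequacyFlags", "SADComparison",
          function(object, options = NULL, ...) {
  opts <- options %||% object@options
  rows <- lapply(object@fits, function(f) {
    data.frame(model = f@model,
               chi2Pass = if (is.na(f@P)) NA else f@P >= opts$alphaLevel,
               r2Pass = if (is.na(f@Rd2)) NA else f@Rd2 >= opts$r2Threshold,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
})

#' Select the best model of a comparison table
#'
#' Ranks the seven fits by one criterion: lowest AIC (`"aic"`), lowest BIC
#' (`"bic"`), highest R_d^2 (`"r2"`), or the combined rule (`"overall"`):
#' lowest AIC among the models passing the chi-square adequacy test,
#' falling back to lowest AIC unconditionally when none pass. Ties are
#' broken by the smaller parameter count, then by the fixed model order
#' GS, BS, ON, LSer, LN, LC, LS. Models with an `NA` score are never
#' selected.
#'
#' @param object a [SADComparison-class].
#' @param criterion `"aic"`, `"bic"`, `"r2"` or `"overall"`.
#' @param ... unused.
#' @return the winning model's name, or `NA` when no model has a defined
#'   score under the criterion.
#' @export
setMethod("selectBest", "SADComparison",
          function(object, criterion = c("aic", "bic", "r2", "overall"),
                   ...) {
  criterion <- match.arg(criterion)
  fits <- object@fits
  score <- switch(criterion,
    aic = vapply(fits, function(f) f@AIC, numeric(1L)),
    bic = vapply(fits, function(f) f@BIC, numeric(1L)),
    r2 = -vapply(fits, function(f) f@Rd2, numeric(1L)),
    overall = {
      aic <- vapply(fits, function(f) f@AIC, numeric(1L))
      pass <- vapply(fits, function(f) isTRUE(f@P >= object@options$alphaLevel),
                     logical(1L))
      if (any(pass)) aic[!pass] <- NA_real_
      aic
    })
  k <- vapply(fits, function(f) as.numeric(f@k), numeric(1L))
  ord <- order(score, k, seq_along(fits), na.last = NA)
  if (!length(ord)) return(NA_character_)
  names(fits)[ord[1L]]
})

#' Observed vs extrapolated richness table
#'
#' For each fitted dataset, the observed total species number S next to the
#' extrapolated totals S* of the five models that support extrapolation
#' (BS, ON, LN, LC, LS), with a flag whether the extrapolation exceeds the
#' observation (S* > S, the minimal sanity requirement for a
#' richness estimate from a left-truncated SAD).
#'
#' @param tables a [SADComparison-class] or a list of them.
#' @return a data.frame with one row per dataset and columns `label, S`,
#'   `Sstar_<model>` and `exceeds_<model>`.
#' @export
richnessTable <- function(tables) {
  if (is(tables, "SADComparison")) tables <- list(tables)
  sstarModels <- c("BS", "ON", "LN", "LC", "LS")
  rows <- lapply(tables, function(tab) {
    S <- sum(tab@fits[[1L]]@observed) + 0  # species entering the histogram
    row <- data.frame(label = tab@label, S = S, stringsAsFactors = FALSE)
    for (m in sstarModels) {
      s <- tab@fits[[m]]@Sstar
      row[[paste0("Sstar_", m)]] <- s
      row[[paste0("exceeds_", m)]] <- if (is.na(s)) NA else s > S
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Serialise fit results to JSON
#'
#' Writes a [SADFit-class] or [SADComparison-class] as a JSON record
#' (parameters, statistics, adequacy-relevant fields) for machine
#' consumption.
#'
#' @param x a SADFit or SADComparison.
#' @param path optional output path; when `NULL` the JSON string is
#'   returned.
#' @return the JSON string (invisibly when written to `path`).
#' @export
fitToJSON <- function(x, path = NULL) {
  payload <- if (is(x, "SADComparison")) {
    list(label = x@label,
         fits = lapply(x@fits, fitRecord),
         best = list(aic = selectBest(x, "aic"), bic = selectBest(x, "bic"),
                     r2 = selectBest(x, "r2"),
                     overall = selectBest(x, "overall")))
  } else fitRecord(x)
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

fitRecord <- function(f) {
  list(model = f@model, params = as.list(f@params),
       n = f@n, k = f@k, SS = f@SS, Rd2 = f@Rd2,
       chi2 = f@chi2, df = f@df, P = f@P, AIC = f@AIC, BIC = f@BIC,
       Sstar = f@Sstar, converged = f@converged, note = f@note)
}
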