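#' One community layer's per-species abundances
#'
#' A \code{LayerDataset} holds the integer abundance (number of individuals)
#' of every species recorded in one layer (pure tree, tree, shrub or herb)
#' of one community plot. It is the unit of analysis: histograms, fits and
#' comparison tables all start from a \code{LayerDataset}.
#'
#' @slot community community label (e.g. a plot code).
#' @slot layer layer label (e.g. \code{"herb"}).
#' @slot species character vector of unique species identifiers.
#' @slot abundance integer vector of per-species counts, all \eqn{\ge 1}.
#' @slot area surveyed area in square metres (\code{NA} if unknown).
#'
#' @seealso [layerDataset()], [binOctaves()], [descriptiveStats()]
#' @export
setClass("LayerDataset",
         representation(community = "character",
                        layer = "character",
                        species = "character",
                        abundance = "integer",
                        area = "numeric"))

setValidity("LayerDataset", function(object) {
  msg <- character()
  if (length(object@species) < 1L)
    msg <- c(msg, "a LayerDataset needs at least one species record")
  if (length(object@species) != length(object@abundance))
    msg <- c(msg, "species and abundance must have equal length")
  if (anyNA(object@abundance) || any(object@abundance < 1L))
    msg <- c(msg, "abundances must be integers >= 1")
  if (any(!nzchar(object@species)) || anyDuplicated(object@species))
    msg <- c(msg, "species identifiers must be non-empty and unique")
  if (length(object@area) != 1L ||
      (!is.na(object@area) && object@area <= 0))
    msg <- c(msg, "area must be a single positive number or NA")
  if (length(msg)) msg else TRUE
})

#' Construct a LayerDataset
#'
#' @param species character vector of species identifiers.
#' @param abundance integer abundances (individuals per species), all >= 1.
#' @param community,layer labels attached to the dataset.
#' @param area surveyed area in m^2, or `NA`.
#' @return a [LayerDataset-class] object.
#' @examples
#' layerDataset(c("a", "b", "c"), c(5, 2, 1), community = "DH", layer = "herb")
#' @export
layerDataset <- function(species, abundance, community = "", layer = "",
                         area = NA_real_) {
  ab <- abundance
  if (is.double(ab)) {
    if (any(is.na(ab)) || any(abs(ab - round(ab)) > 1e-8))
      stop("abundances must be whole numbers (individuals)", call. = FALSE)
    ab <- as.integer(round(ab))
  }
  new("LayerDataset", community = as.character(community),
      layer = as.character(layer), species = as.character(species),
      abundance = as.integer(ab), area = as.numeric(area))
}

#' Octave-binned species counts
#'
#' An \code{OctaveHistogram} stores the number of observed species
#' \eqn{S_{obs}(R)} per octave \eqn{R} (the log2 abundance class), the
#' binning dialect that produced it, and the totals derived from the source
#' dataset. Octaves are contiguous from the smallest to the largest occupied
#' class; interior zero-count octaves are retained because they are data for
#' the regression. Under the Preston boundary-halving dialect counts may be
#' half-integers and the half-species falling below the veil line (abundance
#' class boundary 2^0) are recorded in \code{belowVeil}, never redistributed.
#'
#' @slot octave contiguous integer octave indices.
#' @slot count species count per octave (half-integers allowed under
#'   \code{preston_halving}).
#' @slot dialect \code{"halfopen"} or \code{"preston_halving"}.
#' @slot belowVeil species mass discarded below the veil line.
#' @slot sourceS total species number S of the source dataset.
#' @slot sourceN total individual number N of the source dataset.
#' @slot label dataset label carried through to tables.
#'
#' @seealso [binOctaves()], [modalOctave()], [fitModel()]
#' @export
setClass("OctaveHistogram",
         representation(octave = "integer",
                        count = "numeric",
                        dialect = "character",
                        belowVeil = "numeric",
                        sourceS = "numeric",
                        sourceN = "numeric",
                        label = "character"))

setValidity("OctaveHistogram", function(object) {
  msg <- character()
  if (length(object@octave) < 1L)
    msg <- c(msg, "histogram must contain at least one octave")
  if (length(object@octave) != length(object@count))
    msg <- c(msg, "octave and count must have equal length")
  if (length(object@octave) &&
      !identical(object@octave,
                 seq(object@octave[1L], by = 1L,
                     length.out = length(object@octave))))
    msg <- c(msg, "octaves must be contiguous integers")
  if (any(object@count < 0))
    msg <- c(msg, "species counts must be non-negative")
  if (!object@dialect %in% c("halfopen", "preston_halving"))
    msg <- c(msg, "dialect must be 'halfopen' or 'preston_halving'")
  if (abs(sum(object@count) + object@belowVeil - object@sourceS) > 1e-6)
    msg <- c(msg, "species not conserved: sum(count) + belowVeil != sourceS")
  if (length(msg)) msg else TRUE
})

#' Specification of one SAD model on the octave scale
#'
#' Describes one of the seven supported species-abundance-distribution
#' models: its parameter set, admissible parameter ranges, whether it needs
#' data constants frozen from the histogram (the overlapping-niche model
#' uses the octave-transformed total N_oct and the largest observed octave),
#' and whether a closed-form total-richness extrapolation S* exists.
#'
#' @slot name one of \code{GS, BS, ON, LSer, LN, LC, LS}.
#' @slot k number of free parameters (1, 2 or 3).
#' @slot paramNames ordered parameter labels.
#' @slot lower,upper per-parameter admissible bounds.
#' @slot hasSstar whether S* can be extrapolated.
#' @slot needsDataConstants whether histogram constants are required.
#'
#' @seealso [sadModel()], [sadModels()], [evaluateModel()]
#' @export
setClass("SADModel",
         representation(name = "character",
                        k = "integer",
                        paramNames = "character",
                        lower = "numeric",
                        upper = "numeric",
                        hasSstar = "logical",
                        needsDataConstants = "logical"))

setValidity("SADModel", function(object) {
  msg <- character()
  if (!object@name %in% c("GS", "BS", "ON", "LSer", "LN", "LC", "LS"))
    msg <- c(msg, "unknown model name")
  if (!object@k %in% 1:3)
    msg <- c(msg, "k must be 1, 2 or 3")
  if (length(object@paramNames) != object@k)
    msg <- c(msg, "paramNames must have length k")
  if (length(object@lower) != object@k || length(object@upper) != object@k)
    msg <- c(msg, "bounds must have length k")
  if (length(msg)) msg else TRUE
})

#' Result of fitting one SAD model to one octave histogram
#'
#' Holds the least-squares parameter estimates together with every
#' goodness-of-fit statistic used for model selection: the residual sum of
#' squares, the adjusted coefficient of determination R_d^2, the chi-square
#' test (statistic, degrees of freedom and tail probability P), AIC and BIC,
#' and the extrapolated total richness S* where the model supports it.
#'
#' @slot model model name.
#' @slot params named numeric vector of estimates.
#' @slot dataConstants frozen constants (N_oct, R_max) for the ON model.
#' @slot octave,observed,fitted the octaves, observed and fitted counts.
#' @slot SS residual sum of squares (species^2).
#' @slot n number of octaves entering the regression.
#' @slot k number of free parameters.
#' @slot Rd2 (adjusted) coefficient of determination.
#' @slot chi2,df,P chi-square statistic, degrees of freedom, tail
#'   probability (NA when df < 1).
#' @slot AIC,BIC information criteria (-Inf sentinel for a perfect fit).
#' @slot Sstar extrapolated total richness (NA if unsupported).
#' @slot converged whether the optimiser converged from some start.
#' @slot note diagnostic message (empty when clean).
#'
#' @seealso [fitModel()], [fitAllModels()]
#' @export
setClass("SADFit",
         representation(model = "character",
                        params = "numeric",
                        dataConstants = "numeric",
                        octave = "integer",
                        observed = "numeric",
                        fitted = "numeric",
                        SS = "numeric",
                        n = "integer",
                        k = "integer",
                        Rd2 = "numeric",
                        chi2 = "numeric",
                        df = "numeric",
                        P = "numeric",
                        AIC = "numeric",
                        BIC = "numeric",
                        Sstar = "numeric",
                        converged = "logical",
                        note = "character"))

setValidity("SADFit", function(object) {
  msg <- character()
  if (length(object@SS) == 1L && !is.na(object@SS) && object@SS < 0)
    msg <- c(msg, "SS must be non-negative")
  if (length(object@P) == 1L && !is.na(object@P) &&
      (object@P < 0 || object@P > 1))
    msg <- c(msg, "P must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' All seven model fits for one dataset
#'
#' A \code{SADComparison} bundles the seven [SADFit-class] results obtained
#' for one octave histogram, in the fixed model order GS, BS, ON, LSer, LN,
#' LC, LS, together with the fit options in force. Adequacy flags and
#' best-model selection are derived from it with [adequacyFlags()] and
#' [selectBest()].
#'
#' @slot label dataset label (community / layer).
#' @slot fits named list of seven SADFit objects.
#' @slot options the [fitOptions()] list used.
#'
#' @seealso [fitAllModels()], [richnessTable()]
#' @export
setClass("SADComparison",
         representation(label = "character",
                        fits = "list",
                        options = "list"))

setValidity("SADComparison", function(object) {
  msg <- character()
  if (length(object@fits) != 7L)
    msg <- c(msg, "a SADComparison holds exactly seven model fits")
  if (!all(vapply(object@fits, is, logical(1L), class2 = "SADFit")))
    msg <- c(msg, "all elements of fits must be SADFit objects")
  if (length(msg)) msg else TRUE
})

#' Left-truncated unit-area SAD probability curve
#'
#' The fitted octave-scale curve of one model, truncated on the left at the
#' veil line L and rescaled so that its area over [L, Inf) equals one. Used
#' to compare the commonness/rarity structure of layers and communities on
#' a common probability scale.
#'
#' @slot model model name (LN, LC or LS).
#' @slot params fitted parameters the curve was built from.
#' @slot truncation the truncation octave L.
#' @slot grid ordered octave values >= L.
#' @slot density normalised density at each grid point.
#' @slot label curve label.
#'
#' @seealso [truncatedDensity()], [compareCurves()]
#' @export
setClass("TruncatedCurve",
         representation(model = "character",
                        params = "numeric",
                        truncation = "numeric",
                        grid = "numeric",
                        density = "numeric",
                        label = "character"))

setValidity("TruncatedCurve", function(object) {
  msg <- character()
  if (length(object@grid) != length(object@density))
    msg <- c(msg, "grid and density must have equal length")
  if (any(object@density < 0))
    msg <- c(msg, "density must be non-negative")
  if (length(object@grid) && object@grid[1L] < object@truncation - 1e-9)
    msg <- c(msg, "grid must start at or after the truncation point")
  if (is.unsorted(object@grid, strictly = TRUE))
    msg <- c(msg, "grid must be strictly increasing")
  if (length(msg)) msg else TRUE
})

## ---- accessors and show methods ----

#' @rdname octavesad-generics
#' @export
setMethod("communityName", "LayerDataset", function(object) object@community)

#' @rdname octavesad-generics
#' @export
setMethod("layerName", "LayerDataset", function(object) object@layer)

#' @rdname octavesad-generics
#' @export
setMethod("speciesNames", "LayerDataset", function(object) object@species)

#' @rdname octavesad-generics
#' @export
setMethod("abundances", "LayerDataset", function(object) {
  stats::setNames(object@abundance, object@species)
})

#' @rdname octavesad-generics
#' @export
setMethod("totalSpecies", "LayerDataset",
          function(object) length(object@species))

#' @rdname octavesad-generics
#' @export
setMethod("totalIndividuals", "LayerDataset",
          function(object) sum(object@abundance))

setMethod("show", "LayerDataset", function(object) {
  cat(sprintf("LayerDataset: %s / %s\n",
              if (nzchar(object@community)) object@community else "<community>",
              if (nzchar(object@layer)) object@layer else "<layer>"))
  cat(sprintf("  S = %d species, N = %d individuals (r in [%d, %d])\n",
              totalSpecies(object), totalIndividuals(object),
              min(object@abundance), max(object@abundance)))
  if (!is.na(object@area)) cat(sprintf("  area = %g m^2\n", object@area))
})

#' @rdname octavesad-generics
#' @export
setMethod("octaves", "OctaveHistogram", function(object) object@octave)

#' @rdname octavesad-generics
#' @export
setMethod("octaveCounts", "OctaveHistogram", function(object) {
  stats::setNames(object@count, object@octave)
})

#' @rdname octavesad-generics
#' @export
setMethod("octaveDialect", "OctaveHistogram", function(object) object@dialect)

#' @rdname octavesad-generics
#' @export
setMethod("belowVeil", "OctaveHistogram", function(object) object@belowVeil)

#' @rdname octavesad-generics
#' @export
setMethod("octaveTotal", "OctaveHistogram", function(object) {
  sum(2 ^ object@octave * object@count)
})

setMethod("show", "OctaveHistogram", function(object) {
  cat(sprintf("OctaveHistogram (%s dialect)%s\n", object@dialect,
              if (nzchar(object@label)) paste0(": ", object@label) else ""))
  cat(sprintf("  %d octaves [%d, %d], S = %g, N = %g, N_oct = %g\n",
              length(object@octave), min(object@octave), max(object@octave),
              sum(object@count), object@sourceN, octaveTotal(object)))
  if (object@belowVeil > 0)
    cat(sprintf("  below veil line: %g species\n", object@belowVeil))
  print(octaveCounts(object))
})

#' @rdname octavesad-generics
#' @export
setMethod("modelName", "SADModel", function(object) object@name)

#' @rdname octavesad-generics
#' @export
setMethod("nParameters", "SADModel", function(object) object@k)

setMethod("show", "SADModel", function(object) {
  cat(sprintf("SADModel %s: k = %d (%s)%s\n", object@name, object@k,
              paste(object@paramNames, collapse = ", "),
              if (object@hasSstar) "" else " [no S* extrapolation]"))
})

#' @rdname octavesad-generics
#' @export
setMethod("modelName", "SADFit", function(object) object@model)

#' @rdname octavesad-generics
#' @export
setMethod("parameters", "SADFit", function(object) object@params)

#' @rdname octavesad-generics
#' @export
setMethod("fittedValues", "SADFit", function(object) {
  stats::setNames(object@fitted, object@octave)
})

#' @rdname octavesad-generics
#' @export
setMethod("gofStats", "SADFit", function(object) {
  c(SS = object@SS, Rd2 = object@Rd2, chi2 = object@chi2, df = object@df,
    P = object@P, AIC = object@AIC, BIC = object@BIC, Sstar = object@Sstar)
})

setMethod("show", "SADFit", function(object) {
  cat(sprintf("SADFit: %s model (k = %d) on %d octaves%s\n", object@model,
              object@k, object@n,
              if (object@converged) "" else "  [NOT CONVERGED]"))
  cat("  params: ",
      paste(sprintf("%s = %.4g", names(object@params), object@params),
            collapse = ", "), "\n", sep = "")
  cat(sprintf("  SS = %.4g, R_d^2 = %.3f, chi2 = %.3g (df = %g, P = %s)\n",
              object@SS, object@Rd2, object@chi2, object@df,
              if (is.na(object@P)) "NA" else sprintf("%.3g", object@P)))
  cat(sprintf("  AIC = %.3f, BIC = %.3f%s\n", object@AIC, object@BIC,
              if (is.na(object@Sstar)) ""
              else sprintf(", S* = %.1f", object@Sstar)))
  if (nzchar(object@note)) cat("  note: ", object@note, "\n", sep = "")
})

#' @rdname octavesad-generics
#' @export
setMethod("sadFits", "SADComparison", function(object) object@fits)

setMethod("show", "SADComparison", function(object) {
  cat(sprintf("SADComparison: %s\n",
              if (nzchar(object@label)) object@label else "<unlabelled>"))
  print(as.data.frame(object), digits = 4)
})

#' @rdname octavesad-generics
#' @export
setMethod("parameters", "TruncatedCurve", function(object) object@params)

#' @rdname octavesad-generics
#' @export
setMethod("modelName", "TruncatedCurve", function(object) object@model)

#' @rdname octavesad-generics
#' @export
setMethod("peakHeight", "TruncatedCurve",
          function(object) max(object@density))

setMethod("show", "TruncatedCurve", function(object) {
  cat(sprintf(
    "TruncatedCurve: %s model%s, L = %g, %d grid points, peak = %.4f\n",
    object@model,
    if (nzchar(object@label)) paste0(" (", object@label, ")") else "",
    object@truncation, length(object@grid), peakHeight(object)))
})

#' Flatten fit results to data frames
#'
#' `as.data.frame` on a [SADFit-class] gives the one-row record used for CSV
#' serialisation; on a [SADComparison-class] it stacks the seven rows in the
#' fixed model order.
#'
#' @param x a SADFit or SADComparison.
#' @param row.names,optional,... ignored (S3 compatibility).
#' @return a data.frame.
#' @method as.data.frame SADFit
#' @export
as.data.frame.SADFit <- function(x, row.names = NULL, optional = FALSE, ...) {
  p <- x@params
  data.frame(model = x@model,
             S_m = unname(p["S_m"]),
             alpha = if ("alpha" %in% names(p)) unname(p["alpha"]) else NA_real_,
             R_m = if ("R_m" %in% names(p)) unname(p["R_m"]) else NA_real_,
             n = x@n, k = x@k, SS = x@SS, Rd2 = x@Rd2,
             chi2 = x@chi2, df = x@df, P = x@P,
             AIC = x@AIC, BIC = x@BIC, Sstar = x@Sstar,
             converged = x@converged,
             stringsAsFactors = FALSE)
}

#' @rdname as.data.frame.SADFit
#' @method as.data.frame SADComparison
#' @export
as.data.frame.SADComparison <- function(x, row.names = NULL, optional = FALSE,
                                        ...) {
  out <- do.call(rbind, lapply(x@fits, as.data.frame))
  rownames(out) <- NULL
  out
}

setMethod("as.data.frame", "SADFit", as.data.frame.SADFit)
setMethod("as.data.frame", "SADComparison", as.data.frame.SADComparison)
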