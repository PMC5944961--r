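#' Bin a community's abundances into Preston octaves
#'
#' Groups the per-species abundances of a [LayerDataset-class] into log2
#' abundance classes ("octaves"), in one of two dialects:
#' \describe{
#'   \item{`halfopen`}{octave \eqn{R \ge 1} holds abundances in
#'     \eqn{(2^{R-1}, 2^R]}, with the singletons joining the doubletons in
#'     octave 1 (so R = 1 holds \{1, 2\}, R = 2 holds \{3, 4\}, R = 3 holds
#'     \{5..8\}, ...). Counts are integers and every species is kept. This
#'     is the default.}
#'   \item{`preston_halving`}{class boundaries sit at the powers of two
#'     \eqn{2^0, 2^1, \ldots}; a species with abundance strictly between
#'     \eqn{2^R} and \eqn{2^{R+1}} is counted in octave \eqn{R} (indexed at
#'     the lower boundary) and a species exactly on a boundary \eqn{2^R}
#'     contributes one half to octave \eqn{R - 1} and one half to octave
#'     \eqn{R}. The half of each singleton falling below the smallest
#'     boundary lies below the veil line: it is discarded and reported in
#'     [belowVeil()], never redistributed.}
#' }
#' Interior zero-count octaves are retained — they are data for the
#' regression — and the octave range is contiguous from the smallest to the
#' largest occupied class.
#'
#' @param object a [LayerDataset-class].
#' @param dialect `"halfopen"` (default) or `"preston_halving"`.
#' @param ... unused.
#' @return an [OctaveHistogram-class].
#' @examples
#' ds <- layerDataset(paste0("sp", 1:5), c(1, 1, 2, 3, 5))
#' octaveCounts(binOctaves(ds))                        # 3, 1, 1 at R = 1:3
#' binOctaves(ds, dialect = "preston_halving")
#' @export
setMethod("binOctaves", "LayerDataset",
          function(object, dialect = c("halfopen", "preston_halving"), ...) {
  dialect <- match.arg(dialect)
  r <- object@abundance
  if (length(r) < 1L) stopfNamed("cannot bin an empty dataset")
  lab <- paste(object@community, object@layer)
  lab <- if (nzchar(trimws(lab))) trimws(lab) else ""

  if (dialect == "halfopen") {
    oct <- halfopenOctave(r)
    rng <- seq(min(oct), max(oct))
    cnt <- as.numeric(tabulate(oct - min(oct) + 1L, nbins = length(rng)))
    veil <- 0
  } else {
    ## boundary-halving: accumulate 0.5/1.0 contributions per species
    contrib <- new.env(parent = emptyenv())
    veil <- 0
    add <- function(m, w) {
      key <- as.character(m)
      assign(key, (get0(key, envir = contrib) %||% 0) + w, envir = contrib)
    }
    for (ri in r) {
      if (isPowerOfTwo(ri)) {
        m <- as.integer(round(log2(ri)))
        if (m - 1L < 0L) veil <- veil + 0.5 else add(m - 1L, 0.5)
        add(m, 0.5)
      } else {
        add(as.integer(floor(log2(ri))), 1)
      }
    }
    occ <- as.integer(ls(contrib))
    rng <- seq(min(occ), max(occ))
    cnt <- vapply(rng, function(m)
      get0(as.character(m), envir = contrib) %||% 0, numeric(1L))
  }

  new("OctaveHistogram", octave = as.integer(rng), count = cnt,
      dialect = dialect, belowVeil = veil,
      sourceS = as.numeric(length(r)), sourceN = as.numeric(sum(r)),
      label = lab)
})

#' Modal octave of a histogram
#'
#' The octave with the largest observed species count; ties are broken
#' toward the smallest octave. Observed SADs of left-truncated bell shape
#' typically peak at the first octave.
#'
#' @param object an [OctaveHistogram-class].
#' @return integer octave index.
#' @examples
#' h <- binOctaves(layerDataset(paste0("sp", 1:5), c(1, 1, 2, 3, 5)))
#' modalOctave(h)  # 1
#' @export
setMethod("modalOctave", "OctaveHistogram", function(object) {
  object@octave[which.max(object@count)]
})

#' Descriptive statistics of a community layer
#'
#' Total species number S, total individual number N, and the smallest and
#' largest single-species abundance — the summary row reported for each
#' layer of a surveyed community.
#'
#' @param object a [LayerDataset-class].
#' @param ... unused.
#' @return a one-row data.frame with columns `community, layer, area_m2,
#'   S, N, min_r, max_r`.
#' @examples
#' descriptiveStats(layerDataset(c("a", "b", "c"), c(5, 2, 1)))
#' @export
setMethod("descriptiveStats", "LayerDataset", function(object, ...) {
  data.frame(community = object@community, layer = object@layer,
             area_m2 = object@area,
             S = totalSpecies(object), N = totalIndividuals(object),
             min_r = min(object@abundance), max_r = max(object@abundance),
             stringsAsFactors = FALSE)
})

#' Build an OctaveHistogram directly from octaves and counts
#'
#' Mostly useful for noiseless fixtures (see [expectedHistogram()]) and for
#' re-importing a histogram written by [writeOctaveHistogram()]. The octave
#' range is made contiguous, with zero counts inserted at interior gaps.
#'
#' @param octave integer octave indices.
#' @param count species counts (half-integers allowed).
#' @param dialect binning dialect label.
#' @param sourceN total individuals of the source data; defaults to the
#'   octave-transformed total `sum(2^R * count)`.
#' @param belowVeil species mass below the veil line.
#' @param label dataset label.
#' @return an [OctaveHistogram-class].
#' @export
octaveHistogram <- function(octave, count, dialect = "halfopen",
                            sourceN = NULL, belowVeil = 0, label = "") {
  octave <- as.integer(octave)
  o <- order(octave)
  octave <- octave[o]; count <- as.numeric(count)[o]
  rng <- seq(min(octave), max(octave))
  full <- numeric(length(rng))
  full[match(octave, rng)] <- count
  new("OctaveHistogram", octave = as.integer(rng), count = full,
      dialect = dialect, belowVeil = as.numeric(belowVeil),
      sourceS = sum(full) + belowVeil,
      sourceN = as.numeric(sourceN %||% sum(2 ^ rng * full)),
      label = label)
}
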