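## machine-readable provenance record written by every workflow run
writeProvenance <- function(dir, stage, config) {
  rec <- list(package = "octavesad",
              version = as.character(utils::packageVersion("octavesad")),
              stage = stage, config = config,
              r_version = R.version.string,
              timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE))
  jsonlite::write_json(rec, file.path(dir, paste0(stage, "_provenance.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
}

#' End-to-end fitting workflow
#'
#' Reads a long-format abundance table, bins every (community, layer)
#' dataset, fits the requested models, and writes to `outputDir`: a
#' descriptive-statistics CSV, one per-dataset comparison CSV (the
#' R_d^2/AIC/BIC table layout), a combined richness CSV with the S*
#' extrapolations, a JSON bundle of all fit results, and a provenance
#' record capturing every reproduction-relevant convention in force
#' (dialect, df convention, R^2 variant, thresholds).
#'
#' @param input path to the abundance CSV/TSV.
#' @param outputDir output directory (created if missing).
#' @param dialect binning dialect.
#' @param models models to fit (default all seven).
#' @param options [fitOptions()].
#' @param columns column mapping passed to [readAbundanceTable()].
#' @param verbose print a short narration of the conventions in force.
#' @return invisibly, a list with the comparison tables (full seven-model
#'   runs as [SADComparison-class]) and the output paths.
#' @export
runFit <- function(input, outputDir, dialect = "halfopen",
                   models = modelOrder, options = fitOptions(),
                   columns = c(community = "community", layer = "layer",
                               species = "species", abundance = "abundance"),
                   verbose = TRUE) {
  dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
  datasets <- readAbundanceTable(input, columns = columns)
  if (verbose)
    message(sprintf(
      "fitting %d dataset(s): dialect=%s, df=%s, %s R^2, chi2 at %g, R2 floor %g",
      length(datasets), dialect, options$dfConvention,
      if (options$adjusted) "adjusted" else "plain",
      options$alphaLevel, options$r2Threshold))

  utils::write.csv(descriptiveStatsTable(datasets),
                   file.path(outputDir, "descriptive_stats.csv"),
                   row.names = FALSE, quote = FALSE)

  tables <- lapply(datasets, function(ds) {
    h <- binOctaves(ds, dialect = dialect)
    fitAllModels(h, options = options, models = models)
  })

  paths <- character()
  for (nm in names(tables)) {
    slug <- gsub("[^A-Za-z0-9]+", "_", nm)
    p <- file.path(outputDir, paste0("comparison_", slug, ".csv"))
    utils::write.csv(as.data.frame(tables[[nm]]), p, row.names = FALSE)
    paths <- c(paths, p)
  }

  full <- Filter(function(t) is(t, "SADComparison"), tables)
  if (length(full)) {
    utils::write.csv(richnessTable(unname(full)),
                     file.path(outputDir, "richness.csv"),
                     row.names = FALSE)
    bundle <- lapply(full, function(t)
      jsonlite::fromJSON(fitToJSON(t), simplifyVector = FALSE))
    jsonlite::write_json(bundle, file.path(outputDir, "fits.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
  }
  writeProvenance(outputDir, "fit",
                  list(input = input, dialect = dialect,
                       models = unname(models),
                       dfConvention = options$dfConvention,
                       adjusted = options$adjusted,
                       alphaLevel = options$alphaLevel,
                       r2Threshold = options$r2Threshold,
                       pooling = options$pooling))
  invisible(list(tables = tables, paths = paths, outputDir = outputDir))
}

#' Simulation workflow
#'
#' Generates one synthetic community ([simulateCommunity()]) and writes it
#' as the standard long-format abundance CSV, with the full generator
#' configuration (including the seed) echoed in `#` header comments so an
#' identical file can be regenerated from the header alone.
#'
#' @param out output CSV path.
#' @inheritParams simulateCommunity
#' @return `out`, invisibly.
#' @export
runSimulate <- function(out, model, S, k = NULL, alpha = NULL, R_m = NULL,
                        N = NULL, seed, truncateAtOne = TRUE,
                        multinomial = FALSE, community = "synthetic") {
  ds <- simulateCommunity(model, S = S, k = k, alpha = alpha, R_m = R_m,
                          N = N, seed = seed, truncateAtOne = truncateAtOne,
                          multinomial = multinomial, community = community)
  cfg <- sprintf(
    "octavesad simulate: model=%s S=%d seed=%d truncate_at_one=%s%s",
    normalizeModelName(model), as.integer(S), as.integer(seed),
    truncateAtOne,
    paste0(if (!is.null(k)) sprintf(" k=%g", k),
           if (!is.null(alpha)) sprintf(" alpha=%g", alpha),
           if (!is.null(R_m)) sprintf(" R_m=%g", R_m),
           if (!is.null(N)) sprintf(" N=%g", N)))
  writeAbundanceTable(ds, out, comments = cfg)
  invisible(out)
}

#' Truncated-curve workflow
#'
#' Builds left-truncated unit-area curves from fitted comparison tables
#' (one curve per dataset, using the requested model's fit) and writes the
#' long-format curve CSV plus the comparison summary.
#'
#' @param tables list of [SADComparison-class] objects (e.g. from
#'   [runFit()]`$tables`).
#' @param outputDir output directory.
#' @param model curve model (LN, LC or LS).
#' @param L truncation octave.
#' @param gridN grid resolution.
#' @return invisibly, the list of curves and the comparison report.
#' @export
runCurves <- function(tables, outputDir, model = "LC", L = 0, gridN = 512) {
  dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
  name <- normalizeModelName(model)
  if (!name %in% c("LN", "LC", "LS"))
    stopfNamed("truncated curves are supported for LN, LC and LS only (got %s)",
               name)
  ## common grid so the curves are comparable pointwise
  fits <- lapply(tables, function(t) t@fits[[name]])
  hi <- max(vapply(fits, function(f)
    unname(f@params["R_m"] + 12 / f@params["alpha"]), numeric(1L)))
  grid <- seq(L, hi, length.out = gridN)
  curves <- lapply(seq_along(fits), function(i) {
    lab <- if (!is.null(names(tables)) && nzchar(names(tables)[i]))
      names(tables)[i] else tables[[i]]@label
    truncatedDensity(fits[[i]], L = L, grid = grid, label = lab)
  })
  names(curves) <- vapply(curves, function(cv) cv@label, character(1L))
  writeCurveTable(curves, file.path(outputDir, "curves.csv"))
  report <- compareCurves(curves)
  utils::write.csv(report$summary, file.path(outputDir, "curve_summary.csv"),
                   row.names = FALSE)
  writeProvenance(outputDir, "curves",
                  list(model = name, L = L, gridN = gridN))
  invisible(list(curves = curves, report = report))
}

#' Parameter-recovery workflow
#'
#' Runs [parameterRecovery()] and writes the per-replicate table and the
#' aggregate report to `outputDir`.
#'
#' @param outputDir output directory.
#' @inheritParams parameterRecovery
#' @return invisibly, the recovery report.
#' @export
runRecovery <- function(outputDir, model, S, reps, seed, k = NULL,
                        alpha = NULL, R_m = NULL, N = NULL,
                        dialect = "halfopen", options = fitOptions()) {
  dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
  rep <- parameterRecovery(model, S = S, reps = reps, seed = seed, k = k,
                           alpha = alpha, R_m = R_m, N = N,
                           dialect = dialect, options = options)
  utils::write.csv(rep$replicates,
                   file.path(outputDir, "recovery_replicates.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(bias = as.list(rep$bias), rmse = as.list(rep$rmse),
         selectionRate = rep$selectionRate),
    file.path(outputDir, "recovery_report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeProvenance(outputDir, "recover",
                  list(model = normalizeModelName(model), S = S,
                       reps = reps, seed = seed))
  invisible(rep)
}
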