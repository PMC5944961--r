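#' Read a long-format abundance table
#'
#' Reads a per-species abundance table (one row per species per community
#' layer) from CSV or TSV and splits it into one [LayerDataset-class] per
#' (community, layer) pair, in order of first appearance. Header matching
#' is case-insensitive and the column names are configurable through
#' `columns`, so tables exported from a spreadsheet with other headings can
#' be ingested without editing the file.
#'
#' Abundances must be positive integers; a zero, negative, missing or
#' fractional abundance aborts with an error naming the offending row.
#' Legacy binary spreadsheet files (`.xls`) cannot be parsed directly —
#' export each sheet to CSV and point the reader at those files.
#'
#' @param path path to the table.
#' @param format `"auto"` (by file extension), `"csv"`, `"tsv"` or `"xls"`
#'   (the latter raises an informative error; see Details).
#' @param columns named character vector mapping the roles
#'   `community, layer, species, abundance` to header names in the file.
#' @param area optional named numeric vector of surveyed areas (m^2), named
#'   `"<community> <layer>"`.
#' @return a named list of [LayerDataset-class] objects, named
#'   `"<community> <layer>"`.
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c("community,layer,species,abundance",
#'              "DH,herb,sp1,5", "DH,herb,sp2,2", "DH,herb,sp3,1"), tf)
#' ds <- readAbundanceTable(tf)[[1]]
#' totalSpecies(ds); totalIndividuals(ds)
#' @export
readAbundanceTable <- function(path,
                               format = c("auto", "csv", "tsv", "xls"),
                               columns = c(community = "community",
                                           layer = "layer",
                                           species = "species",
                                           abundance = "abundance"),
                               area = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stopfNamed("input file not found: %s", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, tsv = "tsv", txt = "tsv", xls = "xls",
                     xlsx = "xls", "csv")
  }
  if (format == "xls")
    stopfNamed(paste("binary spreadsheet input is not supported:",
                     "export each sheet of '%s' to CSV/TSV and read those"),
               basename(path))
  sep <- if (format == "tsv") "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, comment.char = "#",
                           quote = "\"", fileEncoding = "UTF-8")

  need <- c("community", "layer", "species", "abundance")
  if (!all(need %in% names(columns)))
    stopfNamed("columns mapping must name: %s", paste(need, collapse = ", "))
  idx <- match(tolower(columns[need]), tolower(names(tab)))
  if (anyNA(idx))
    stopfNamed("missing column(s) in %s: %s", basename(path),
               paste(columns[need][is.na(idx)], collapse = ", "))
  df <- tab[, idx]
  names(df) <- need

  ab <- suppressWarnings(as.numeric(df$abundance))
  bad <- which(is.na(ab) | ab < 1 | abs(ab - round(ab)) > 1e-8)
  if (length(bad))
    stopfNamed("invalid abundance at data row %d (species '%s'): %s",
               bad[1L], df$species[bad[1L]],
               as.character(df$abundance[bad[1L]]))

  key <- paste(df$community, df$layer)
  out <- lapply(split(seq_len(nrow(df)), factor(key, levels = unique(key))),
                function(i) {
                  k <- key[i[1L]]
                  layerDataset(df$species[i], ab[i],
                               community = df$community[i[1L]],
                               layer = df$layer[i[1L]],
                               area = if (!is.null(area) && k %in% names(area))
                                 area[[k]] else NA_real_)
                })
  out
}

#' Write an octave histogram to CSV
#'
#' Emits the two-column `(octave, species_count)` table; the dialect,
#' source totals and any below-veil mass are recorded as `#` comment lines
#' so the file is self-describing.
#'
#' @param h an [OctaveHistogram-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeOctaveHistogram <- function(h, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# dialect: %s", h@dialect), con)
  writeLines(sprintf("# S: %g  N: %g  below_veil: %g",
                     h@sourceS, h@sourceN, h@belowVeil), con)
  utils::write.table(
    data.frame(octave = h@octave, species_count = h@count),
    con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a community as a long-format abundance CSV
#'
#' The inverse of [readAbundanceTable()] for a single layer; extra header
#' comment lines (e.g. the generator seed) can be prepended.
#'
#' @param ds a [LayerDataset-class].
#' @param path output file path.
#' @param comments character vector of comment lines (written as `# ...`).
#' @return `path`, invisibly.
#' @export
writeAbundanceTable <- function(ds, path, comments = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments)) writeLines(paste("#", comments), con)
  utils::write.table(
    data.frame(community = communityName(ds), layer = layerName(ds),
               species = speciesNames(ds), abundance = unname(abundances(ds))),
    con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Descriptive-statistics table for several layers
#'
#' Stacks [descriptiveStats()] over a list of datasets into the summary
#' table reported for a survey (one row per community layer).
#'
#' @param datasets list of [LayerDataset-class] objects.
#' @return a data.frame with one row per dataset.
#' @export
descriptiveStatsTable <- function(datasets) {
  out <- do.call(rbind, lapply(datasets, descriptiveStats))
  rownames(out) <- NULL
  out
}
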