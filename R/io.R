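## Tabular I/O. All writers can embed the run-config hash as a leading
## comment line; all readers skip '#' comment lines.

.hashHeader <- function(config) {
  if (is.null(config)) character(0)
  else paste0("# ftsascreen config=", configHash(config))
}

.writeTable <- function(df, path, sep, config = NULL, extra = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  for (line in c(.hashHeader(config), extra)) writeLines(line, con)
  utils::write.table(df, con, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

.readTable <- function(path, sep) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.table(path, sep = sep, header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read a melt-curve instrument export
#'
#' Two CSV dialects are accepted. \code{long}: columns \code{well},
#' \code{temperature}, \code{fluorescence}, one row per acquisition point.
#' \code{wide}: a \code{temperature} column plus one column per well. All
#' wells must share one strictly increasing temperature grid; duplicate well
#' ids are rejected, and a non-monotone temperature column is rejected with
#' the offending line number.
#'
#' @param path CSV file path.
#' @param dialect \code{"long"} or \code{"wide"}.
#' @return A \code{\link{MeltCurveSet}}.
#' @export
readMeltExport <- function(path, dialect = c("long", "wide")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readLines(path)
  skip <- sum(cumprod(startsWith(raw, "#")))      # leading comment lines
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE,
                        stringsAsFactors = FALSE)
  headerLine <- skip + 1L
  if (dialect == "long") {
    need <- c("well", "temperature", "fluorescence")
    if (!all(need %in% colnames(df)))
      stop("long dialect needs columns: ", paste(need, collapse = ", "))
    wells <- unique(df$well)
    ref <- df$temperature[df$well == wells[1]]
    bad <- which(diff(ref) <= 0)
    if (length(bad)) {
      row <- which(df$well == wells[1])[bad[1] + 1L]
      stop("non-monotone temperature at line ", headerLine + row)
    }
    mat <- matrix(NA_real_, nrow = length(ref), ncol = length(wells),
                  dimnames = list(NULL, wells))
    for (wl in wells) {
      rows <- df[df$well == wl, ]
      if (nrow(rows) != length(ref) ||
          max(abs(rows$temperature - ref)) > 1e-8)
        stop("well ", wl, " does not share the common temperature grid")
      if (anyDuplicated(rows$temperature))
        stop("duplicate temperature rows for well ", wl)
      mat[, wl] <- rows$fluorescence
    }
    return(MeltCurveSet(mat, ref))
  }
  if (!"temperature" %in% colnames(df))
    stop("wide dialect needs a 'temperature' column")
  wells <- colnames(df)[colnames(df) != "temperature"]
  if (anyDuplicated(wells))
    stop("duplicate well ids: ",
         paste(unique(wells[duplicated(wells)]), collapse = ", "))
  bad <- which(diff(df$temperature) <= 0)
  if (length(bad))
    stop("non-monotone temperature at line ", headerLine + bad[1] + 1L)
  mat <- as.matrix(df[, wells, drop = FALSE])
  MeltCurveSet(mat, df$temperature)
}

#' Write a melt-curve export
#'
#' @param x A \code{\link{MeltCurveSet}}.
#' @param path Output CSV path.
#' @param dialect \code{"long"} (canonical interchange) or \code{"wide"}.
#' @param config Optional \code{\link{runConfig}}; its hash is embedded as a
#'   comment line.
#' @return The path, invisibly.
#' @export
writeMeltExport <- function(x, path, dialect = c("long", "wide"),
                            config = NULL) {
  dialect <- match.arg(dialect)
  stopifnot(is(x, "MeltCurveSet"))
  temp <- temperatures(x)
  fl <- fluorescence(x)
  if (dialect == "long") {
    df <- data.frame(
      well = rep(colnames(fl), each = length(temp)),
      temperature = rep(temp, times = ncol(fl)),
      fluorescence = as.vector(fl), stringsAsFactors = FALSE)
  } else {
    df <- data.frame(temperature = temp, fl, check.names = FALSE)
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (line in .hashHeader(config)) writeLines(line, con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a plate map
#'
#' Plate maps are TSV renderings of a \code{\link{ScreenPlan}}'s well table;
#' the stage travels in a comment line so the round trip is lossless.
#'
#' @param plan A \code{\link{ScreenPlan}}.
#' @param path TSV path.
#' @param config Optional \code{\link{runConfig}} for the provenance hash.
#' @return \code{writePlateMap}: the path; \code{readPlateMap}: a
#'   \code{ScreenPlan}.
#' @export
writePlateMap <- function(plan, path, config = NULL) {
  stopifnot(is(plan, "ScreenPlan"))
  .writeTable(planWells(plan), path, sep = "\t", config = config,
              extra = paste0("# stage=", planStage(plan)))
}

#' @rdname writePlateMap
#' @export
readPlateMap <- function(path) {
  raw <- readLines(path, n = 10L)
  stageLine <- grep("^# stage=", raw, value = TRUE)
  stage <- if (length(stageLine)) sub("^# stage=", "", stageLine[1]) else "pooled"
  w <- .readTable(path, sep = "\t")
  for (col in c("content", "protein"))
    w[[col]] <- ifelse(w[[col]] %in% c("NA", ""), NA_character_,
                       as.character(w[[col]]))
  new("ScreenPlan", stage = stage, wells = w)
}

#' Read / write a ligand library table
#'
#' TSV with columns \code{ligandId}, \code{name}, \code{category},
#' \code{solvent}, optional \code{stockNote}; validated on read.
#'
#' @param path TSV path.
#' @param ligandLibrary Library data.frame.
#' @param config Optional \code{\link{runConfig}}.
#' @export
readLigandLibrary <- function(path) {
  .validateLibrary(.readTable(path, sep = "\t"))
}

#' @rdname readLigandLibrary
#' @export
writeLigandLibrary <- function(ligandLibrary, path, config = NULL) {
  .validateLibrary(ligandLibrary)
  .writeTable(ligandLibrary, path, sep = "\t", config = config)
}

#' Write / read a per-well Tm table
#'
#' @param tmTable Table from \code{\link{callTmSet}}.
#' @param path TSV path.
#' @param config Optional \code{\link{runConfig}}.
#' @export
writeTmTable <- function(tmTable, path, config = NULL) {
  .writeTable(tmTable, path, sep = "\t", config = config)
}

#' @rdname writeTmTable
#' @export
readTmTable <- function(path) .readTable(path, sep = "\t")

#' Write / read binding calls
#'
#' @param calls Binding-call table from \code{\link{bindingCalls}}.
#' @param path TSV path.
#' @param config Optional \code{\link{runConfig}}.
#' @export
writeBindingCalls <- function(calls, path, config = NULL) {
  .writeTable(calls, path, sep = "\t", config = config)
}

#' @rdname writeBindingCalls
#' @export
readBindingCalls <- function(path) .readTable(path, sep = "\t")

#' Read an evidence table
#'
#' TSV with columns \code{protein}, \code{sources} (semicolon-separated
#' subset of literature, genome_context, annotation_description,
#' pdb_homology, other) and \code{ftsaQuality} (good/marginal).
#'
#' @param path TSV path.
#' @return data.frame with a parsed \code{sourceList} list-column.
#' @export
readEvidence <- function(path) {
  df <- .readTable(path, sep = "\t")
  stopifnot(all(c("protein", "sources", "ftsaQuality") %in% colnames(df)))
  df$sourceList <- lapply(strsplit(as.character(df$sources), ";"),
                          function(s) s[nzchar(s)])
  df
}

#' Write a per-target binding-profile report
#'
#' One row per target with its strongest ligands (at most \code{n}, ranked
#' by mean delta-Tm) rendered as \code{"ligand (deltaTm)"}, the profile
#' categories, and the evidence tier when supplied.
#'
#' @param calls Binding-call table.
#' @param path TSV path.
#' @param ligandLibrary Optional library for category lookup.
#' @param tiers Optional named character vector, protein -> tier.
#' @param n Ligands per target (default 4).
#' @param config Optional \code{\link{runConfig}}.
#' @return The report data.frame, invisibly written to \code{path}.
#' @export
writeBindingProfile <- function(calls, path, ligandLibrary = NULL,
                                tiers = NULL, n = 4L, config = NULL) {
  rows <- lapply(unique(calls$protein), function(p) {
    top <- topLigands(calls[calls$protein == p, , drop = FALSE], n)
    lig <- if (nrow(top))
      paste(sprintf("%s (%.1f)", top$content, top$meanDeltaTm),
            collapse = "; ") else ""
    cats <- if (!is.null(ligandLibrary) && nrow(top))
      paste(sort(unique(ligandLibrary$category[
        match(top$content, ligandLibrary$ligandId)])), collapse = ";") else ""
    data.frame(target = p, nBinding = nrow(top), ligands = lig,
               categories = cats,
               tier = if (!is.null(tiers) && p %in% names(tiers))
                 tiers[[p]] else "", stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  .writeTable(report, path, sep = "\t", config = config)
  invisible(report)
}

#' Write a JSON run summary
#'
#' @param summary Named list of run-level quantities.
#' @param path JSON path.
#' @param config Optional \code{\link{runConfig}}; its hash is embedded in
#'   the JSON.
#' @export
writeRunSummary <- function(summary, path, config = NULL) {
  if (!is.null(config)) summary$configHash <- configHash(config)
  jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write simulation ground truth as JSON
#'
#' @param x A simulated \code{\link{MeltCurveSet}}.
#' @param path JSON path.
#' @export
writeGroundTruth <- function(x, path) {
  gt <- metadata(x)$groundTruth
  if (is.null(gt)) stop("no ground truth attached to this MeltCurveSet")
  jsonlite::write_json(gt, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
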