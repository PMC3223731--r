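.EVIDENCE_SOURCES <- c("literature", "genome_context",
                       "annotation_description", "pdb_homology", "other")

#' Assign a data-verification tier from external evidence
#'
#' Functional assignments are tiered by how much independent evidence backs
#' the thermal-shift result: \code{High} needs good-quality assay data plus
#' two or more external validation sources (literature, genome context,
#' annotation/description, PDB homology, ...); one source gives
#' \code{Moderate}; good-quality assay data alone gives \code{Low}. Marginal
#' assay data with no external support gets no tier (NA, a QC annotation).
#' Duplicate source entries never change the tier.
#'
#' @param sources Character vector of evidence sources (a set; duplicates and
#'   unknown entries are dropped with a warning for unknowns).
#' @param ftsaQuality \code{"good"} or \code{"marginal"}.
#' @return \code{"High"}, \code{"Moderate"}, \code{"Low"} or \code{NA}.
#' @examples
#' assignTier(c("literature", "genome_context"), "good")   # High
#' assignTier("genome_context", "good")                    # Moderate
#' assignTier(character(0), "good")                        # Low
#' @export
assignTier <- function(sources, ftsaQuality = c("good", "marginal")) {
  ftsaQuality <- match.arg(ftsaQuality)
  sources <- unique(sources[!is.na(sources) & nzchar(sources)])
  unknown <- setdiff(sources, .EVIDENCE_SOURCES)
  if (length(unknown)) {
    warning("unknown evidence source(s) ignored: ",
            paste(unknown, collapse = ", "))
    sources <- intersect(sources, .EVIDENCE_SOURCES)
  }
  n <- length(sources)
  if (n >= 2 && ftsaQuality == "good") return("High")
  if (n >= 1) return("Moderate")
  if (ftsaQuality == "good") return("Low")
  NA_character_
}

#' Compare predicted and observed ligand categories for one protein
#'
#' The prediction (from annotation or COG class) is compared at the category
#' level against the categories of all ligands the protein bound. Outcomes:
#' \code{consistent} (predicted category among observed), \code{inconsistent},
#' \code{no_prediction}, or \code{no_binding}.
#'
#' @param protein Protein id.
#' @param predicted Predicted ligand category (NA/empty for none).
#' @param calls Binding-call table for the protein (per-ligand rows).
#' @param categoryMap Named character vector mapping ligand id to category;
#'   must cover every binding ligand.
#' @return One-row data.frame: \code{protein}, \code{predicted},
#'   \code{observed} (semicolon-joined), \code{outcome}.
#' @export
compareAnnotation <- function(protein, predicted, calls, categoryMap) {
  b <- calls[calls$verdict == "binding" & calls$protein == protein, ,
             drop = FALSE]
  if (!nrow(b)) {
    outcome <- "no_binding"
    observed <- character(0)
  } else {
    unmapped <- setdiff(b$content, names(categoryMap))
    if (length(unmapped))
      stop("ligand(s) missing from category map: ",
           paste(unmapped, collapse = ", "))
    observed <- sort(unique(unname(categoryMap[b$content])))
    outcome <- if (is.na(predicted) || !nzchar(predicted)) "no_prediction"
      else if (predicted %in% observed) "consistent" else "inconsistent"
  }
  data.frame(protein = protein,
             predicted = if (is.na(predicted)) NA_character_ else predicted,
             observed = paste(observed, collapse = ";"),
             outcome = outcome, stringsAsFactors = FALSE)
}

#' Annotation-consistency report over a target set
#'
#' @param predictions data.frame: \code{protein}, \code{predicted}.
#' @param calls Binding-call table (all proteins).
#' @param categoryMap Named ligand-to-category map.
#' @return List: \code{comparisons} (one row per protein) and
#'   \code{consistencyRate} (fraction of targets with consistent outcome,
#'   in [0, 1]).
#' @export
annotationReport <- function(predictions, calls, categoryMap) {
  rows <- lapply(seq_len(nrow(predictions)), function(i)
    compareAnnotation(predictions$protein[i], predictions$predicted[i],
                      calls, categoryMap))
  comparisons <- do.call(rbind, rows)
  list(comparisons = comparisons,
       consistencyRate = mean(comparisons$outcome == "consistent"))
}

#' Per-category binder counts
#'
#' Counts, for each ligand category, the distinct proteins whose top binding
#' profile (strongest \code{n} ligands) includes that category. A protein
#' binding ligands from several categories counts in each of them.
#'
#' @param calls Binding-call table (all proteins).
#' @param ligandLibrary Ligand library with \code{ligandId} and
#'   \code{category}.
#' @param n Profile depth per protein (default 4).
#' @return Named integer vector of protein counts per category (all library
#'   categories, zeros included).
#' @export
categoryProfile <- function(calls, ligandLibrary, n = 4L) {
  .validateLibrary(ligandLibrary)
  cats <- sort(unique(ligandLibrary$category))
  counts <- setNames(integer(length(cats)), cats)
  for (p in unique(calls$protein)) {
    top <- topLigands(calls[calls$protein == p, , drop = FALSE], n)
    if (!nrow(top)) next
    pc <- unique(ligandLibrary$category[match(top$content,
                                              ligandLibrary$ligandId)])
    pc <- pc[!is.na(pc)]
    counts[pc] <- counts[pc] + 1L
  }
  counts
}
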