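#' Match a sample well to its no-ligand control
#'
#' Each plate carries protein-only negative controls; a sample well's
#' reference Tm is the mean over ok-flagged protein-only replicates of the
#' same protein. Controls on the sample's plate with the sample's solvent
#' class are preferred (a 2% DMSO reaction is compared against a 2% DMSO
#' control, since DMSO can itself shift the midpoint); otherwise any-solvent
#' same-plate, then off-plate controls are used with a mismatch note.
#'
#' @param sample One-row data.frame (a sample row of a Tm table).
#' @param tmTable Tm table from \code{\link{callTmSet}} containing the
#'   protein-only control rows.
#' @return List: \code{tm} (NA on failure), \code{solvent}, \code{note}
#'   (\code{""}, \code{"solvent_mismatch"}, \code{"off_plate"} or
#'   \code{"no_control"}).
#' @export
matchControl <- function(sample, tmTable) {
  ctrl <- tmTable[tmTable$role == "protein_only" &
                  tmTable$protein == sample$protein &
                  tmTable$flag == "ok", , drop = FALSE]
  if (!nrow(ctrl))
    return(list(tm = NA_real_, solvent = NA_character_, note = "no_control"))
  pick <- function(rows, note) {
    list(tm = mean(rows$tm), solvent = rows$solvent[1], note = note)
  }
  samePlate <- ctrl[ctrl$plate == sample$plate, , drop = FALSE]
  if (nrow(samePlate)) {
    m <- samePlate[samePlate$solvent == sample$solvent, , drop = FALSE]
    if (nrow(m)) return(pick(m, ""))
    return(pick(samePlate, "solvent_mismatch"))
  }
  m <- ctrl[ctrl$solvent == sample$solvent, , drop = FALSE]
  if (nrow(m)) return(pick(m, "off_plate"))
  pick(ctrl, "off_plate_solvent_mismatch")
}

#' Melting-midpoint shift of a sample relative to its control
#'
#' \code{deltaTm = sampleTm - controlTm}, signed: destabilization is
#' negative. Either input being unavailable (NA, from a well without a clear
#' melt) yields NA, which downstream classification treats as a QC failure.
#'
#' @param sampleTm,controlTm Melting midpoints, degC.
#' @return Numeric delta-Tm (degC), NA where undefined.
#' @examples
#' deltaTm(72, 55)   # 17
#' @export
deltaTm <- function(sampleTm, controlTm) {
  if (!is.numeric(sampleTm) || !is.numeric(controlTm))
    stop("melting midpoints must be numeric")
  sampleTm - controlTm
}

#' Average duplicate delta-Tm measurements
#'
#' Duplicated reactions are summarized by the arithmetic mean; the spread
#' (max - min) is retained and flagged when it reaches 2 degC, the level at
#' which duplicate variability stops being typical for this assay.
#'
#' @param values Numeric vector of delta-Tm values (>= 1, NAs dropped).
#' @return List: \code{mean}, \code{spread}, \code{n},
#'   \code{highVariability}.
#' @examples
#' averageReplicates(c(16.8, 17.2))
#' @export
averageReplicates <- function(values) {
  values <- values[!is.na(values)]
  if (!length(values)) stop("no replicate values to average")
  spread <- max(values) - min(values)
  list(mean = mean(values), spread = spread, n = length(values),
       highVariability = spread >= 2)
}

#' Classify binding from a mean delta-Tm
#'
#' A ligand is called binding when the averaged midpoint shift is 2 degC or
#' greater (threshold inclusive). Negative shifts (destabilization) are never
#' binding.
#'
#' @param meanDeltaTm Numeric vector of averaged shifts (degC).
#' @param threshold Binding threshold, degC (default 2).
#' @return Character vector: \code{"binding"} / \code{"no_binding"}, with
#'   \code{"qc_fail"} where the shift is NA.
#' @examples
#' classifyBinding(c(2, 1.99, 17, -5))
#' @export
classifyBinding <- function(meanDeltaTm, threshold = 2.0) {
  if (!is.numeric(meanDeltaTm)) stop("meanDeltaTm must be numeric")
  out <- ifelse(meanDeltaTm >= threshold, "binding", "no_binding")
  out[is.na(meanDeltaTm)] <- "qc_fail"
  out
}

#' Binding calls for every (protein, content) pair of a Tm table
#'
#' Runs the control matching, delta-Tm computation, replicate averaging and
#' threshold classification over a per-well Tm table. A pair is
#' \code{qc_fail} when no replicate yields a defined delta-Tm (no clear melt,
#' or no control for the protein).
#'
#' @param tmTable Per-well Tm table from \code{\link{callTmSet}}.
#' @param threshold Binding threshold, degC.
#' @return data.frame: \code{protein}, \code{content}, \code{contentType},
#'   \code{meanDeltaTm}, \code{spread}, \code{n}, \code{controlTm},
#'   \code{controlSolvent}, \code{verdict}, \code{notes}.
#' @export
bindingCalls <- function(tmTable, threshold = 2.0) {
  need <- c("plate", "protein", "content", "contentType", "solvent",
            "replicate", "role", "tm", "flag")
  stopifnot(all(need %in% colnames(tmTable)))
  samples <- tmTable[tmTable$role == "sample", , drop = FALSE]
  if (!nrow(samples))
    return(data.frame(protein = character(0), content = character(0),
                      contentType = character(0), meanDeltaTm = numeric(0),
                      spread = numeric(0), n = integer(0),
                      controlTm = numeric(0), controlSolvent = character(0),
                      verdict = character(0), notes = character(0),
                      stringsAsFactors = FALSE))
  samples$deltaTm <- NA_real_
  samples$ctrlTm <- NA_real_
  samples$ctrlSolvent <- NA_character_
  samples$note <- ""
  for (i in seq_len(nrow(samples))) {
    ctl <- matchControl(samples[i, ], tmTable)
    samples$ctrlTm[i] <- ctl$tm
    samples$ctrlSolvent[i] <- ctl$solvent
    samples$note[i] <- ctl$note
    if (!is.na(ctl$tm) && samples$flag[i] == "ok")
      samples$deltaTm[i] <- deltaTm(samples$tm[i], ctl$tm)
  }
  groups <- split(samples, paste(samples$protein, samples$content, sep = "\r"))
  rows <- lapply(groups, function(g) {
    ok <- !is.na(g$deltaTm)
    notes <- setdiff(unique(g$note), "")
    if (!any(ok)) {
      return(data.frame(protein = g$protein[1], content = g$content[1],
                        contentType = g$contentType[1],
                        meanDeltaTm = NA_real_, spread = NA_real_,
                        n = 0L, controlTm = NA_real_,
                        controlSolvent = NA_character_, verdict = "qc_fail",
                        notes = paste(c(notes, "no_usable_replicate"),
                                      collapse = ";"),
                        stringsAsFactors = FALSE))
    }
    avg <- averageReplicates(g$deltaTm[ok])
    if (avg$highVariability) notes <- c(notes, "high_variability")
    data.frame(protein = g$protein[1], content = g$content[1],
               contentType = g$contentType[1], meanDeltaTm = avg$mean,
               spread = avg$spread, n = avg$n,
               controlTm = g$ctrlTm[ok][1],
               controlSolvent = g$ctrlSolvent[ok][1],
               verdict = classifyBinding(avg$mean, threshold),
               notes = paste(notes, collapse = ";"), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$protein, out$content), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Strongest binding ligands of one protein
#'
#' Binding calls sorted by mean delta-Tm (descending), truncated to the
#' \code{n} strongest; ties resolve by ligand id so output is deterministic.
#' This is the per-target summary convention: at most four ligands reported.
#'
#' @param calls Binding-call data.frame for one protein.
#' @param n Maximum ligands reported (default 4).
#' @return The top rows of \code{calls}, binding verdicts only.
#' @export
topLigands <- function(calls, n = 4L) {
  b <- calls[calls$verdict == "binding", , drop = FALSE]
  b <- b[order(-b$meanDeltaTm, b$content), , drop = FALSE]
  utils::head(b, n)
}

.FUNNEL_STAGES <- c("cloned", "expressed", "soluble_small", "soluble_scaled",
                    "purified", "screened", "ligand_assigned")

#' Pipeline funnel summary from per-target stage outcomes
#'
#' Summarizes attrition from cloning to ligand assignment. Stage outcomes
#' must be monotone per target (a protein cannot be screened without being
#' purified); non-monotone rows are rejected by id.
#'
#' @param status data.frame with a \code{target} column and logical columns
#'   \code{cloned}, \code{expressed}, \code{soluble_small},
#'   \code{soluble_scaled}, \code{purified}, \code{screened},
#'   \code{ligand_assigned}.
#' @return List: \code{stages} (data.frame of stage, count, percent of all
#'   targets) and \code{assignedOfScreened} (percent of screened targets with
#'   a ligand assigned).
#' @export
funnelSummary <- function(status) {
  stopifnot("target" %in% colnames(status),
            all(.FUNNEL_STAGES %in% colnames(status)))
  m <- as.matrix(status[, .FUNNEL_STAGES])
  storage.mode(m) <- "integer"
  bad <- which(apply(m, 1L, function(r) any(diff(r) > 0)))
  if (length(bad))
    stop("non-monotone stage outcome for target(s): ",
         paste(status$target[bad], collapse = ", "))
  counts <- colSums(m)
  stages <- data.frame(stage = .FUNNEL_STAGES,
                       count = as.integer(counts),
                       percent = 100 * counts / nrow(status),
                       row.names = NULL, stringsAsFactors = FALSE)
  screened <- counts[["screened"]]
  assignedOfScreened <- if (screened > 0)
    100 * counts[["ligand_assigned"]] / screened else 0
  list(stages = stages, assignedOfScreened = assignedOfScreened)
}
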