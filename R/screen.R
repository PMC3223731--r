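## stock solvent class -> reaction-well solvent class
.wellSolvent <- function(stock) {
  unname(c(hepes_ph7.5 = "aqueous", dmso = "dmso2pct",
           hepes_ph10 = "nonstandard_pH", hepes_ph1.5 = "nonstandard_pH")[stock])
}

.validateLibrary <- function(ligandLibrary) {
  need <- c("ligandId", "name", "category", "solvent")
  if (!all(need %in% colnames(ligandLibrary)))
    stop("ligand library must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(ligandLibrary$ligandId))
    stop("duplicate ligand ids in library")
  if (any(is.na(ligandLibrary$category) | !nzchar(ligandLibrary$category)))
    stop("every ligand needs a nonempty category")
  bad <- !ligandLibrary$solvent %in% .STOCK_SOLVENTS
  if (any(bad))
    stop("unknown solvent class for ligand(s): ",
         paste(ligandLibrary$ligandId[bad], collapse = ", "))
  invisible(ligandLibrary)
}

#' Build ligand pools from a library
#'
#' Partitions the ligand library into pools of at most \code{maxSize}
#' members, grouping by (chemical category, stock solvent) so pool members
#' share chemistry and are solvent-compatible. Groups larger than
#' \code{maxSize} are split into balanced, ligand-id-ordered pools (a
#' 25-member group at the default size yields pools of 9/8/8). Ligands whose
#' stocks sit at nonstandard pH are never pooled with others and become
#' singleton pools. Every ligand lands in exactly one pool.
#'
#' @param ligandLibrary data.frame: \code{ligandId}, \code{name},
#'   \code{category}, \code{solvent} (one of hepes_ph7.5, dmso, hepes_ph10,
#'   hepes_ph1.5), optional \code{stockNote}.
#' @param maxSize Maximum pool size (default 10).
#' @return data.frame: \code{poolId}, \code{ligandId}, \code{category},
#'   \code{solvent}.
#' @export
buildPools <- function(ligandLibrary, maxSize = 10L) {
  .validateLibrary(ligandLibrary)
  stopifnot(maxSize >= 1L)
  lib <- ligandLibrary[order(ligandLibrary$category, ligandLibrary$solvent,
                             ligandLibrary$ligandId), , drop = FALSE]
  nonstd <- lib$solvent %in% c("hepes_ph10", "hepes_ph1.5")
  groups <- c(
    split(lib[!nonstd, , drop = FALSE],
          paste(lib$category[!nonstd], lib$solvent[!nonstd], sep = "\r"),
          drop = TRUE),
    split(lib[nonstd, , drop = FALSE], lib$ligandId[nonstd], drop = TRUE)
  )
  groups <- groups[order(names(groups))]
  out <- list()
  id <- 0L
  for (g in groups) {
    n <- nrow(g)
    k <- ceiling(n / maxSize)
    sizes <- rep(floor(n / k), k)
    extra <- n %% k
    if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    at <- 1L
    for (s in sizes) {
      id <- id + 1L
      rows <- g[at:(at + s - 1L), , drop = FALSE]
      out[[id]] <- data.frame(poolId = sprintf("pool%03d", id),
                              ligandId = rows$ligandId,
                              category = rows$category,
                              solvent = rows$solvent,
                              stringsAsFactors = FALSE)
      at <- at + s
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Ligand concentration for a reaction
#'
#' Standard reactions run at a 100x ligand-to-protein ratio (e.g. 500 uM
#' ligand with 5 uM protein, 1000 uM with 10 uM). Fatty-acid ligands, whose
#' dye background at 100x swamps the protein signal, run at 10x (40 uM ligand
#' with 4 uM protein).
#'
#' @param proteinConc Protein concentration, uM; by default one of 4, 5, 10.
#' @param ligand A one-row library record (with \code{category}) or a
#'   category string.
#' @param allowedConc Permitted protein concentrations (extensible).
#' @return Ligand concentration, uM.
#' @examples
#' planConcentrations(10, "amino_acid")   # 1000
#' planConcentrations(4, "fatty_acid")    # 40
#' @export
planConcentrations <- function(proteinConc, ligand,
                               allowedConc = c(4, 5, 10)) {
  if (!is.numeric(proteinConc) || length(proteinConc) != 1L ||
      !is.finite(proteinConc) || proteinConc <= 0)
    stop("proteinConc must be a positive scalar")
  if (!proteinConc %in% allowedConc)
    stop("proteinConc must be one of: ", paste(allowedConc, collapse = ", "))
  category <- if (is.data.frame(ligand)) ligand$category[1] else as.character(ligand)
  ratio <- if (identical(category, "fatty_acid")) 10 else 100
  ratio * proteinConc
}

.WELL_LABELS <- as.vector(t(outer(LETTERS[1:8], 1:12, paste0)))

## Greedy row-major plate layout. reactions: protein, contentType, content,
## ligandConc, solvent, replicate. Controls per plate: duplicate protein-only
## wells per protein (aqueous, plus DMSO-matched when the plate carries 2%
## DMSO reactions for that protein), one buffer-only and one dye-only well.
.controlRows <- function(reactions, proteinConc) {
  prot <- unique(reactions$protein)
  rows <- list()
  for (p in prot) {
    for (r in 1:2)
      rows[[length(rows) + 1L]] <- data.frame(
        protein = p, contentType = "none", content = NA_character_,
        proteinConc = proteinConc, ligandConc = NA_real_,
        solvent = "aqueous", replicate = r, role = "protein_only",
        stringsAsFactors = FALSE)
    if (any(reactions$protein == p & reactions$solvent == "dmso2pct"))
      for (r in 1:2)
        rows[[length(rows) + 1L]] <- data.frame(
          protein = p, contentType = "none", content = NA_character_,
          proteinConc = proteinConc, ligandConc = NA_real_,
          solvent = "dmso2pct", replicate = r, role = "protein_only",
          stringsAsFactors = FALSE)
  }
  rows[[length(rows) + 1L]] <- data.frame(
    protein = NA_character_, contentType = "none", content = NA_character_,
    proteinConc = NA_real_, ligandConc = NA_real_, solvent = "aqueous",
    replicate = 1L, role = "buffer_only", stringsAsFactors = FALSE)
  rows[[length(rows) + 1L]] <- data.frame(
    protein = NA_character_, contentType = "none", content = NA_character_,
    proteinConc = NA_real_, ligandConc = NA_real_, solvent = "aqueous",
    replicate = 1L, role = "dye_only", stringsAsFactors = FALSE)
  do.call(rbind, rows)
}

.layoutPlan <- function(reactions, proteinConc, stage,
                        platePrefix = "P", plateSize = 96L) {
  if (!nrow(reactions)) stop("no sample reactions to lay out")
  reactions$role <- "sample"
  plates <- list()
  current <- reactions[0, , drop = FALSE]
  flush <- function() {
    if (!nrow(current)) return(invisible())
    plateId <- paste0(platePrefix, length(plates) + 1L)
    ctrl <- .controlRows(current, proteinConc)
    block <- rbind(current, ctrl)
    block$plate <- plateId
    block$well <- .WELL_LABELS[seq_len(nrow(block))]
    plates[[length(plates) + 1L]] <<- block
  }
  for (i in seq_len(nrow(reactions))) {
    candidate <- rbind(current, reactions[i, , drop = FALSE])
    total <- nrow(candidate) + nrow(.controlRows(candidate, proteinConc))
    if (total > plateSize && nrow(current)) {
      flush()
      current <- reactions[i, , drop = FALSE]
    } else {
      current <- candidate
    }
  }
  flush()
  wells <- do.call(rbind, plates)
  wells <- wells[, .PLAN_COLS]
  rownames(wells) <- NULL
  new("ScreenPlan", stage = stage, wells = wells)
}

#' Plan the pooled first-pass screen
#'
#' One sample well per (protein, pool), each protein screened against all
#' pools so every protein has an equal chance to bind every ligand. Pools
#' with DMSO stocks enter at 2% final DMSO and are paired with DMSO-matched
#' protein-only controls on the same plate. Plans overflow onto additional
#' 96-well plates, each carrying its own negative controls.
#'
#' @param proteins Character vector of protein ids.
#' @param pools Pool table from \code{\link{buildPools}}.
#' @param proteinConc Protein concentration, uM.
#' @param plateSize Wells per plate (default 96).
#' @return A \code{\link{ScreenPlan}} with stage \code{"pooled"}.
#' @export
planPooledStage <- function(proteins, pools, proteinConc = 10,
                            plateSize = 96L) {
  if (!length(proteins)) stop("no proteins to screen")
  poolIds <- unique(pools$poolId)
  if (!length(poolIds)) stop("no pools to screen: plan rejected")
  poolCat <- pools$category[match(poolIds, pools$poolId)]
  poolSol <- pools$solvent[match(poolIds, pools$poolId)]
  rx <- expand.grid(poolIdx = seq_along(poolIds), protein = proteins,
                    stringsAsFactors = FALSE)
  reactions <- data.frame(
    protein = rx$protein,
    contentType = "pool",
    content = poolIds[rx$poolIdx],
    proteinConc = proteinConc,
    ligandConc = vapply(poolCat[rx$poolIdx], function(cc)
      planConcentrations(proteinConc, cc), numeric(1)),
    solvent = .wellSolvent(poolSol[rx$poolIdx]),
    replicate = 1L,
    stringsAsFactors = FALSE)
  reactions <- reactions[order(reactions$protein, reactions$content), ]
  .layoutPlan(reactions, proteinConc, stage = "pooled", platePrefix = "P",
              plateSize = plateSize)
}

#' Plan the deconvolution stage from pooled hits
#'
#' For every (protein, pool) pooled call with a binding verdict, schedules a
#' re-test of the pool plus one well per member ligand at its per-category
#' concentration. Nothing is scheduled for proteins without pooled hits.
#'
#' @param pooledCalls Binding-call table from the pooled stage.
#' @param pools Pool table from \code{\link{buildPools}}.
#' @param ligandLibrary Ligand library (per-member categories).
#' @param proteinConc Protein concentration, uM.
#' @param replicates Wells per follow-up reaction (default 1; the screen
#'   orchestrator duplicates positives by passing 2).
#' @param plateSize Wells per plate.
#' @return A \code{\link{ScreenPlan}} with stage \code{"deconvolution"}, or
#'   \code{NULL} when there are no pooled hits.
#' @export
deconvolute <- function(pooledCalls, pools, ligandLibrary, proteinConc = 10,
                        replicates = 1L, plateSize = 96L) {
  .validateLibrary(ligandLibrary)
  hits <- pooledCalls[pooledCalls$verdict == "binding" &
                      pooledCalls$contentType == "pool", , drop = FALSE]
  if (!nrow(hits)) return(NULL)
  unknown <- setdiff(hits$content, pools$poolId)
  if (length(unknown))
    stop("pool id absent from pool table: ", paste(unknown, collapse = ", "))
  rows <- list()
  for (i in seq_len(nrow(hits))) {
    pid <- hits$content[i]
    prot <- hits$protein[i]
    members <- pools[pools$poolId == pid, , drop = FALSE]
    poolConc <- planConcentrations(proteinConc, members$category[1])
    for (r in seq_len(replicates)) {
      rows[[length(rows) + 1L]] <- data.frame(
        protein = prot, contentType = "pool", content = pid,
        proteinConc = proteinConc, ligandConc = poolConc,
        solvent = .wellSolvent(members$solvent[1]), replicate = r,
        stringsAsFactors = FALSE)
      for (j in seq_len(nrow(members))) {
        lig <- ligandLibrary[ligandLibrary$ligandId == members$ligandId[j], ]
        rows[[length(rows) + 1L]] <- data.frame(
          protein = prot, contentType = "ligand", content = lig$ligandId,
          proteinConc = proteinConc,
          ligandConc = planConcentrations(proteinConc, lig$category),
          solvent = .wellSolvent(lig$solvent), replicate = r,
          stringsAsFactors = FALSE)
      }
    }
  }
  reactions <- do.call(rbind, rows)
  .layoutPlan(reactions, proteinConc, stage = "deconvolution",
              platePrefix = "D", plateSize = plateSize)
}

#' Call one screening stage from curves and its plan
#'
#' Aligns planned wells to the curves available for them, calls Tm per well
#' and classifies delta-Tm against matched controls. A planned well with no
#' curve is carried as a QC failure; the stage still completes.
#'
#' @param curves A \code{\link{MeltCurveSet}} covering the plan's wells.
#' @param plan The \code{\link{ScreenPlan}} that produced them.
#' @param threshold Binding threshold, degC.
#' @param ... Passed to \code{\link{callTm}}.
#' @return List: \code{tmTable} (per well) and \code{calls} (per
#'   protein-content pair).
#' @export
screenStage <- function(curves, plan, threshold = 2.0, ...) {
  stopifnot(is(curves, "MeltCurveSet"), is(plan, "ScreenPlan"))
  w <- planWells(plan)
  keys <- paste(w$plate, w$well, sep = ":")
  temp <- temperatures(curves)
  fl <- fluorescence(curves)
  res <- lapply(keys, function(k) {
    if (k %in% colnames(fl)) callTm(temp, fl[, k], ...)
    else data.frame(tm = NA_real_, extremum = NA_real_, amplitude = 0,
                    flag = "missing_curve", secondary = 0L,
                    stringsAsFactors = FALSE)
  })
  tmTable <- cbind(w, do.call(rbind, res))
  rownames(tmTable) <- NULL
  list(tmTable = tmTable, calls = bindingCalls(tmTable, threshold))
}

#' Run the two-step pooled screen end to end on simulated plates
#'
#' Orchestrates the full workflow: build pools, plan and simulate the pooled
#' first pass, call pooled hits, plan and simulate the deconvolution stage
#' (every positive reaction independently duplicated), and classify the final
#' per-ligand binding calls.
#'
#' @param proteins Character vector of protein ids.
#' @param ligandLibrary Ligand library data.frame.
#' @param truths Ground-truth table (\code{protein}, \code{ligand},
#'   \code{kd}).
#' @param params Named list of \code{\link{thermoParams}} per protein.
#' @param profile \code{\link{instrumentProfile}}.
#' @param seed Root seed for both simulated stages.
#' @param threshold Binding threshold, degC.
#' @param proteinConc Protein concentration, uM.
#' @param poolMaxSize Maximum pool size.
#' @return List: \code{pools}, \code{pooledPlan}, \code{pooledCalls},
#'   \code{deconvPlan}, \code{deconvCalls}, \code{final} (per-ligand binding
#'   calls from the deconvolution stage).
#' @export
runScreen <- function(proteins, ligandLibrary, truths, params,
                      profile = instrumentProfile(), seed = 1,
                      threshold = 2.0, proteinConc = 10, poolMaxSize = 10L) {
  pools <- buildPools(ligandLibrary, poolMaxSize)
  pooledPlan <- planPooledStage(proteins, pools, proteinConc)
  mcs1 <- simulatePlate(pooledPlan, truths, params, profile,
                        ligandLibrary = ligandLibrary, pools = pools,
                        seed = seed)
  st1 <- screenStage(mcs1, pooledPlan, threshold)
  dplan <- deconvolute(st1$calls, pools, ligandLibrary, proteinConc,
                       replicates = 2L)
  if (is.null(dplan)) {
    empty <- st1$calls[0, , drop = FALSE]
    return(list(pools = pools, pooledPlan = pooledPlan,
                pooledCalls = st1$calls, deconvPlan = NULL,
                deconvCalls = empty, final = empty))
  }
  mcs2 <- simulatePlate(dplan, truths, params, profile,
                        ligandLibrary = ligandLibrary, pools = pools,
                        seed = seed)
  st2 <- screenStage(mcs2, dplan, threshold)
  final <- st2$calls[st2$calls$contentType == "ligand", , drop = FALSE]
  rownames(final) <- NULL
  list(pools = pools, pooledPlan = pooledPlan, pooledCalls = st1$calls,
       deconvPlan = dplan, deconvCalls = st2$calls, final = final)
}

#' Exhaustive single-ligand reference screen
#'
#' Screens every (protein, ligand) pair individually, bypassing pooling.
#' Serves as the reference against which the two-step pooled screen is
#' checked for equivalence on noise-free simulations.
#'
#' @inheritParams runScreen
#' @param replicates Wells per reaction.
#' @return List: \code{plan}, \code{tmTable}, \code{calls}.
#' @export
exhaustiveScreen <- function(proteins, ligandLibrary, truths, params,
                             profile = instrumentProfile(), seed = 1,
                             threshold = 2.0, proteinConc = 10,
                             replicates = 1L) {
  .validateLibrary(ligandLibrary)
  rows <- list()
  for (p in proteins)
    for (j in seq_len(nrow(ligandLibrary)))
      for (r in seq_len(replicates)) {
        lig <- ligandLibrary[j, ]
        rows[[length(rows) + 1L]] <- data.frame(
          protein = p, contentType = "ligand", content = lig$ligandId,
          proteinConc = proteinConc,
          ligandConc = planConcentrations(proteinConc, lig$category),
          solvent = .wellSolvent(lig$solvent), replicate = r,
          stringsAsFactors = FALSE)
      }
  plan <- .layoutPlan(do.call(rbind, rows), proteinConc,
                      stage = "exhaustive", platePrefix = "X")
  mcs <- simulatePlate(plan, truths, params, profile,
                       ligandLibrary = ligandLibrary, seed = seed)
  st <- screenStage(mcs, plan, threshold)
  list(plan = plan, tmTable = st$tmTable, calls = st$calls)
}
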