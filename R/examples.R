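## Synthetic example inputs. These emulate the shape of a real screening
## campaign -- a chemically categorized ligand library, a target registry of
## solute-binding plus efflux-associated proteins, and per-stage production
## outcomes -- without any experimental data behind them.

.EXAMPLE_CATEGORIES <- c(
  "metal", "amino_acid", "fatty_acid", "dicarboxylic_acid", "aromatic_acid",
  "lignin_monomer", "polyamine", "vitamin", "peptide", "sugar",
  "sugar_acid", "sugar_alcohol", "phosphate", "phosphonate", "purine",
  "pyrimidine", "nucleoside", "nucleotide", "urea", "sulfate", "sulfonate",
  "nitrate", "siderophore", "organic_acid", "alcohol", "amide", "amine",
  "osmolyte", "quaternary_amine", "cofactor", "oxyanion", "thiol", "halide")

#' Synthetic ligand library
#'
#' A deterministic, synthetic screening library spanning 33 chemical
#' categories (the breadth of a typical environmental/metabolite library),
#' \code{perCategory} ligands each. Aromatic acids and lignin monomers stock
#' in DMSO; one purine stocks at pH 10 and one amino acid at pH 1.5
#' (nonstandard-pH handling); everything else stocks in HEPES pH 7.5.
#'
#' @param perCategory Ligands per category (default 3).
#' @return Ligand-library data.frame: \code{ligandId}, \code{name},
#'   \code{category}, \code{solvent}, \code{stockNote}.
#' @export
exampleLigandLibrary <- function(perCategory = 3L) {
  rows <- list()
  for (ci in seq_along(.EXAMPLE_CATEGORIES)) {
    cat <- .EXAMPLE_CATEGORIES[ci]
    for (j in seq_len(perCategory)) {
      id <- sprintf("L%02d%02d", ci, j)
      solvent <- if (cat %in% c("aromatic_acid", "lignin_monomer")) "dmso"
        else if (cat == "purine" && j == 1L) "hepes_ph10"
        else if (cat == "amino_acid" && j == perCategory) "hepes_ph1.5"
        else "hepes_ph7.5"
      rows[[length(rows) + 1L]] <- data.frame(
        ligandId = id, name = paste0(cat, "_", j), category = cat,
        solvent = solvent, stockNote = "synthetic", stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Synthetic target registry
#'
#' The 108-protein target registry of a genome-scale binding-protein
#' campaign: 105 solute-binding protein candidates plus 3 efflux-associated
#' membrane fusion proteins. Ids are synthetic.
#'
#' @return data.frame: \code{target}, \code{class} (sbp/mfp).
#' @export
exampleTargetRegistry <- function() {
  data.frame(
    target = c(sprintf("SBP%03d", 1:105), sprintf("MFP%03d", 106:108)),
    class = c(rep("sbp", 105), rep("mfp", 3)),
    stringsAsFactors = FALSE)
}

#' Synthetic production-funnel outcomes
#'
#' Per-target stage outcomes for the 108-target registry, with attrition
#' rates typical of a high-throughput production pipeline for this protein
#' family: 107 cloned, 105 expressed, 94 soluble at small scale, 77 at
#' large scale, 75 purified and screened, 48 with a ligand assigned. Stage
#' outcomes are monotone by construction.
#'
#' @return data.frame suitable for \code{\link{funnelSummary}}.
#' @export
exampleFunnelStatus <- function() {
  reg <- exampleTargetRegistry()
  n <- nrow(reg)
  cutoffs <- c(cloned = 107L, expressed = 105L, soluble_small = 94L,
               soluble_scaled = 77L, purified = 75L, screened = 75L,
               ligand_assigned = 48L)
  out <- data.frame(target = reg$target, stringsAsFactors = FALSE)
  for (s in names(cutoffs)) out[[s]] <- seq_len(n) <= cutoffs[[s]]
  out
}

#' Small synthetic screening scenario
#'
#' A compact, fully specified scenario for demos and pipeline checks:
#' \code{nProteins} proteins with staggered melting midpoints, a reduced
#' library, and planted ground-truth binders with prescribed midpoint shifts
#' (via \code{\link{kdForShift}}).
#'
#' @param nProteins Number of proteins (default 3).
#' @param perCategory Ligands per library category (default 1).
#' @param shifts Named numeric vector of planted shifts, degC; names are
#'   \code{"<protein index>:<ligand index>"} pairs into the protein and
#'   library orderings. Default plants one strong binder per protein.
#' @return List: \code{proteins}, \code{ligandLibrary}, \code{params}
#'   (named list of \code{\link{thermoParams}}), \code{truths}.
#' @export
exampleScreenSetup <- function(nProteins = 3L, perCategory = 1L,
                               shifts = NULL) {
  proteins <- sprintf("SBP%03d", seq_len(nProteins))
  lib <- exampleLigandLibrary(perCategory)
  params <- lapply(seq_len(nProteins), function(i)
    thermoParams(tm0 = 50 + 3 * ((i - 1L) %% 5L)))
  names(params) <- proteins
  if (is.null(shifts)) {
    shifts <- setNames(rep(8, nProteins),
                       paste(seq_len(nProteins), seq_len(nProteins), sep = ":"))
  }
  truths <- do.call(rbind, lapply(names(shifts), function(k) {
    idx <- as.integer(strsplit(k, ":")[[1]])
    prot <- proteins[idx[1]]
    lig <- lib[idx[2], ]
    conc <- planConcentrations(10, lig$category)
    data.frame(protein = prot, ligand = lig$ligandId,
               kd = kdForShift(params[[prot]], shifts[[k]], conc),
               bindsNative = TRUE, stringsAsFactors = FALSE)
  }))
  list(proteins = proteins, ligandLibrary = lib, params = params,
       truths = truths)
}
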