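#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom stats setNames
#' @import SummarizedExperiment
NULL

## Solvent classes a reaction well can carry. Stocks in 100% DMSO enter the
## assay at 2% final DMSO; guanine/hypoxanthine-style stocks at nonstandard pH
## enter at 2% of the nonstandard buffer.
.WELL_SOLVENTS <- c("aqueous", "dmso2pct", "nonstandard_pH")

## Solvent classes of ligand stocks in the library.
.STOCK_SOLVENTS <- c("hepes_ph7.5", "dmso", "hepes_ph10", "hepes_ph1.5")

.WELL_ROLES <- c("sample", "protein_only", "buffer_only", "dye_only")

#' Two-state unfolding parameters for one protein
#'
#' Parameterizes a single cooperative melt transition: the reference melting
#' midpoint \code{tm0}, the apparent van 't Hoff enthalpy \code{dhVH}
#' controlling transition sharpness, linear native and unfolded fluorescence
#' baselines, and an exponential post-transition signal decay (SYPRO-orange
#' signal is lost above the transition as dye dissociates).
#'
#' @slot tm0 Reference melting midpoint, degrees C.
#' @slot dhVH Apparent van 't Hoff unfolding enthalpy, kJ/mol (> 0).
#' @slot nativeBaseline Numeric length 2: intercept (fluorescence units) and
#'   slope (units per degree C) of the folded-state baseline.
#' @slot unfoldedBaseline Numeric length 2: intercept and slope of the
#'   unfolded-state baseline.
#' @slot postPeakDecay Rate of fluorescence loss above the transition (1/degC,
#'   >= 0).
#' @export
setClass("ThermoParams",
  representation(
    tm0 = "numeric",
    dhVH = "numeric",
    nativeBaseline = "numeric",
    unfoldedBaseline = "numeric",
    postPeakDecay = "numeric"
  )
)

setValidity("ThermoParams", function(object) {
  msg <- character()
  vals <- c(object@tm0, object@dhVH, object@nativeBaseline,
            object@unfoldedBaseline, object@postPeakDecay)
  if (!all(is.finite(vals)))
    msg <- c(msg, "all thermodynamic parameters must be finite")
  if (length(object@tm0) != 1L || length(object@dhVH) != 1L ||
      length(object@postPeakDecay) != 1L)
    msg <- c(msg, "tm0, dhVH and postPeakDecay must be scalars")
  if (length(object@nativeBaseline) != 2L || length(object@unfoldedBaseline) != 2L)
    msg <- c(msg, "baselines must be length-2 (intercept, slope)")
  if (length(msg)) return(msg)
  if (object@dhVH <= 0)
    msg <- c(msg, "dhVH must be > 0")
  if (object@postPeakDecay < 0)
    msg <- c(msg, "postPeakDecay must be >= 0")
  nat <- object@nativeBaseline[1] + object@nativeBaseline[2] * object@tm0
  unf <- object@unfoldedBaseline[1] + object@unfoldedBaseline[2] * object@tm0
  if (!(unf > nat))
    msg <- c(msg, "unfolded baseline must exceed native baseline at tm0")
  if (length(msg)) msg else TRUE
})

#' Construct ThermoParams
#'
#' Defaults describe a well-behaved mid-size (30-40 kDa) solute-binding
#' protein: midpoint 55 degC, apparent van 't Hoff enthalpy 450 kJ/mol, a low
#' flat native baseline and a high unfolded plateau with mild post-peak decay.
#'
#' @param tm0 Melting midpoint (degC).
#' @param dhVH Apparent van 't Hoff enthalpy (kJ/mol).
#' @param nativeBaseline,unfoldedBaseline Length-2 numeric, intercept and
#'   slope in fluorescence units and units/degC.
#' @param postPeakDecay Post-transition decay rate (1/degC).
#' @return A \code{ThermoParams} object.
#' @examples
#' thermoParams(tm0 = 60)
#' @export
thermoParams <- function(tm0 = 55, dhVH = 450,
                         nativeBaseline = c(200, -0.5),
                         unfoldedBaseline = c(2600, -0.5),
                         postPeakDecay = 0.002) {
  new("ThermoParams", tm0 = as.numeric(tm0), dhVH = as.numeric(dhVH),
      nativeBaseline = as.numeric(nativeBaseline),
      unfoldedBaseline = as.numeric(unfoldedBaseline),
      postPeakDecay = as.numeric(postPeakDecay))
}

#' @describeIn thermoParams Melting midpoint accessor.
#' @param object A \code{ThermoParams} object.
#' @export
tm0 <- function(object) object@tm0

#' @describeIn thermoParams van 't Hoff enthalpy accessor (kJ/mol).
#' @export
dhVH <- function(object) object@dhVH

setMethod("show", "ThermoParams", function(object) {
  cat("ThermoParams: tm0 =", object@tm0, "degC, dhVH =", object@dhVH,
      "kJ/mol\n  native baseline", paste(object@nativeBaseline, collapse = " + T*"),
      "; unfolded", paste(object@unfoldedBaseline, collapse = " + T*"),
      "; post-peak decay", object@postPeakDecay, "/degC\n")
})

#' Acquisition profile of a melt-curve instrument
#'
#' Describes the temperature ramp and signal characteristics of a qPCR-style
#' instrument used for thermal-shift acquisition: ramp window, sampling
#' density, a systematic offset of the apparent melting midpoint relative to a
#' reference instrument, and the additive fluorescence noise scale.
#'
#' @slot name Instrument name.
#' @slot tempStart Ramp start (degC).
#' @slot tempSpan Ramp span (degC, > 0).
#' @slot pointsPerDegree Acquisition density (points per degC, >= 1).
#' @slot tmOffset Systematic shift of the apparent melting midpoint (degC).
#' @slot noiseSD Additive Gaussian fluorescence noise, standard deviation in
#'   fluorescence units.
#' @export
setClass("InstrumentProfile",
  representation(
    name = "character",
    tempStart = "numeric",
    tempSpan = "numeric",
    pointsPerDegree = "numeric",
    tmOffset = "numeric",
    noiseSD = "numeric"
  )
)

setValidity("InstrumentProfile", function(object) {
  msg <- character()
  if (!all(is.finite(c(object@tempStart, object@tempSpan,
                       object@pointsPerDegree, object@tmOffset, object@noiseSD))))
    msg <- c(msg, "numeric profile fields must be finite")
  else {
    if (object@tempSpan <= 0) msg <- c(msg, "tempSpan must be > 0")
    if (object@pointsPerDegree < 1) msg <- c(msg, "pointsPerDegree must be >= 1")
    if (object@noiseSD < 0) msg <- c(msg, "noiseSD must be >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an instrument profile
#'
#' Two presets are provided. \code{"lightcycler480"} acquires 30 points per
#' degree over a 70 degC ramp (2101 points inclusive) and is the reference
#' frame for melting midpoints. \code{"mx4000"} is a sparser legacy profile
#' whose apparent midpoints read 3 degC lower, emulating the systematic
#' between-instrument difference seen when the same reactions are run on both
#' machines; delta-Tm values are unaffected by this offset.
#'
#' @param name Preset name, or any name when all fields are given explicitly.
#' @param tempStart,tempSpan Ramp window (degC).
#' @param pointsPerDegree Sampling density (1/degC).
#' @param tmOffset Apparent-midpoint offset (degC).
#' @param noiseSD Additive fluorescence noise SD.
#' @return An \code{InstrumentProfile}.
#' @examples
#' instrumentProfile()                      # LightCycler-like default
#' instrumentProfile("mx4000")
#' @export
instrumentProfile <- function(name = "lightcycler480", tempStart = NULL,
                              tempSpan = NULL, pointsPerDegree = NULL,
                              tmOffset = NULL, noiseSD = NULL) {
  preset <- switch(name,
    lightcycler480 = list(tempStart = 25, tempSpan = 70, pointsPerDegree = 30,
                          tmOffset = 0, noiseSD = 5),
    mx4000 = list(tempStart = 25, tempSpan = 70, pointsPerDegree = 2,
                  tmOffset = -3, noiseSD = 5),
    list(tempStart = 25, tempSpan = 70, pointsPerDegree = 30,
         tmOffset = 0, noiseSD = 5)
  )
  pick <- function(x, d) if (is.null(x)) d else as.numeric(x)
  new("InstrumentProfile", name = name,
      tempStart = pick(tempStart, preset$tempStart),
      tempSpan = pick(tempSpan, preset$tempSpan),
      pointsPerDegree = pick(pointsPerDegree, preset$pointsPerDegree),
      tmOffset = pick(tmOffset, preset$tmOffset),
      noiseSD = pick(noiseSD, preset$noiseSD))
}

#' Temperature grid of an instrument profile
#'
#' @param profile An \code{InstrumentProfile}.
#' @return Numeric vector of acquisition temperatures (degC), inclusive of
#'   both ramp ends.
#' @export
temperatureGrid <- function(profile) {
  stopifnot(is(profile, "InstrumentProfile"))
  n <- round(profile@tempSpan * profile@pointsPerDegree)
  profile@tempStart + seq(0L, n) / profile@pointsPerDegree
}

setMethod("show", "InstrumentProfile", function(object) {
  cat("InstrumentProfile '", object@name, "': ", object@tempStart, "-",
      object@tempStart + object@tempSpan, " degC, ", object@pointsPerDegree,
      " pts/degC, tmOffset ", object@tmOffset, " degC, noiseSD ",
      object@noiseSD, "\n", sep = "")
})

#' Container for a plate of melt curves
#'
#' A \code{MeltCurveSet} extends \code{SummarizedExperiment}: the
#' \code{"fluorescence"} assay holds one column per well over a shared,
#' strictly increasing temperature grid stored in \code{rowData(x)$temperature}.
#' Well metadata (protein, content, concentrations, solvent, replicate, role,
#' plate) lives in \code{colData}; the instrument profile, root seed and any
#' simulation ground truth live in \code{metadata}.
#'
#' @export
setClass("MeltCurveSet", contains = "SummarizedExperiment")

setValidity("MeltCurveSet", function(object) {
  msg <- character()
  if (!"fluorescence" %in% assayNames(object))
    return("assay 'fluorescence' is required")
  if (!"temperature" %in% colnames(rowData(object)))
    return("rowData column 'temperature' is required")
  temp <- rowData(object)$temperature
  if (!all(is.finite(temp)) || any(diff(temp) <= 0))
    msg <- c(msg, "temperatures must be finite and strictly increasing")
  if (!all(is.finite(assay(object, "fluorescence"))))
    msg <- c(msg, "fluorescence values must be finite")
  if (length(msg)) msg else TRUE
})

#' Construct a MeltCurveSet
#'
#' @param fluorescence Numeric matrix, temperatures x wells; column names are
#'   well keys and must be unique.
#' @param temperature Strictly increasing numeric vector, one per row.
#' @param wellData A \code{data.frame}/\code{DataFrame} of per-well metadata
#'   (one row per column of \code{fluorescence}).
#' @param profile Optional \code{InstrumentProfile} stored in metadata.
#' @param ... Further metadata entries (e.g. \code{seed}, \code{groundTruth}).
#' @return A \code{MeltCurveSet}.
#' @export
MeltCurveSet <- function(fluorescence, temperature, wellData = NULL,
                         profile = NULL, ...) {
  fluorescence <- as.matrix(fluorescence)
  if (ncol(fluorescence) && is.null(colnames(fluorescence)))
    stop("fluorescence matrix must have well names as column names")
  if (is.null(colnames(fluorescence)))
    colnames(fluorescence) <- character(0)
  if (anyDuplicated(colnames(fluorescence)))
    stop("duplicate well ids: ",
         paste(unique(colnames(fluorescence)[duplicated(colnames(fluorescence))]),
               collapse = ", "))
  if (is.null(wellData))
    wellData <- DataFrame(well = colnames(fluorescence))
  se <- SummarizedExperiment(
    assays = list(fluorescence = fluorescence),
    rowData = DataFrame(temperature = as.numeric(temperature)),
    colData = as(wellData, "DataFrame")
  )
  md <- list(profile = profile, ...)
  metadata(se) <- md[!vapply(md, is.null, logical(1))]
  new("MeltCurveSet", se)
}

#' @describeIn MeltCurveSet Shared temperature grid (degC).
#' @param x A \code{MeltCurveSet}.
#' @export
temperatures <- function(x) rowData(x)$temperature

#' @describeIn MeltCurveSet Fluorescence matrix (temperatures x wells).
#' @export
fluorescence <- function(x) assay(x, "fluorescence")

#' @describeIn MeltCurveSet Per-well metadata as a data.frame.
#' @export
wellData <- function(x) as.data.frame(colData(x))

setMethod("show", "MeltCurveSet", function(object) {
  temp <- temperatures(object)
  cat("MeltCurveSet:", ncol(object), "wells x", nrow(object), "points (",
      min(temp), "-", max(temp), "degC )\n")
  prof <- metadata(object)$profile
  if (!is.null(prof)) cat("  instrument:", prof@name, "\n")
  if (!is.null(metadata(object)$groundTruth))
    cat("  simulation ground truth attached\n")
})

#' Plate-level screening plan
#'
#' Ordered reaction wells for one stage of the two-step screen (pooled first
#' pass or single-ligand deconvolution), with plate assignments. Validity
#' requires every plate to carry the negative controls run alongside samples:
#' a protein-only control for each protein on the plate, a buffer-only well
#' and a dye-only well.
#'
#' @slot stage \code{"pooled"} or \code{"deconvolution"} (or
#'   \code{"exhaustive"} for reference single-ligand screens).
#' @slot wells data.frame of reaction wells: plate, well, protein, contentType
#'   (none/ligand/pool), content, proteinConc, ligandConc, solvent, replicate,
#'   role.
#' @export
setClass("ScreenPlan",
  representation(stage = "character", wells = "data.frame"))

.PLAN_COLS <- c("plate", "well", "protein", "contentType", "content",
                "proteinConc", "ligandConc", "solvent", "replicate", "role")

setValidity("ScreenPlan", function(object) {
  w <- object@wells
  msg <- character()
  if (!object@stage %in% c("pooled", "deconvolution", "exhaustive"))
    msg <- c(msg, "stage must be pooled, deconvolution or exhaustive")
  if (!all(.PLAN_COLS %in% colnames(w)))
    return(paste("wells must have columns:", paste(.PLAN_COLS, collapse = ", ")))
  if (nrow(w)) {
    if (!all(w$role %in% .WELL_ROLES))
      msg <- c(msg, "unknown well role")
    if (!all(w$solvent %in% c(.WELL_SOLVENTS, NA)))
      msg <- c(msg, "unknown solvent class")
    bad <- w$role == "protein_only" & w$contentType != "none"
    if (any(bad)) msg <- c(msg, "protein_only wells must have no content")
    smp <- w$role == "sample"
    if (any(smp & (!is.finite(w$proteinConc) | w$proteinConc <= 0)))
      msg <- c(msg, "sample wells need proteinConc > 0")
    if (any(smp & (!is.finite(w$ligandConc) | w$ligandConc <= 0)))
      msg <- c(msg, "sample wells need ligandConc > 0")
    for (p in unique(w$plate)) {
      pw <- w[w$plate == p, ]
      prot <- unique(pw$protein[pw$role == "sample"])
      ctrl <- unique(pw$protein[pw$role == "protein_only"])
      if (!all(prot %in% ctrl))
        msg <- c(msg, paste0("plate ", p, " lacks protein-only controls"))
      if (length(prot) &&
          (!any(pw$role == "buffer_only") || !any(pw$role == "dye_only")))
        msg <- c(msg, paste0("plate ", p, " lacks buffer/dye controls"))
    }
    key <- paste(w$plate, w$well)
    if (anyDuplicated(key))
      msg <- c(msg, "duplicate (plate, well) assignment")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn ScreenPlan Reaction-well table accessor.
#' @param plan A \code{ScreenPlan}.
#' @export
planWells <- function(plan) plan@wells

#' @describeIn ScreenPlan Stage accessor.
#' @export
planStage <- function(plan) plan@stage

setMethod("show", "ScreenPlan", function(object) {
  w <- object@wells
  cat("ScreenPlan (", object@stage, "): ", nrow(w), " wells on ",
      length(unique(w$plate)), " plate(s); ",
      sum(w$role == "sample"), " samples, ",
      sum(w$role != "sample"), " controls\n", sep = "")
})
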