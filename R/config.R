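#' Run configuration
#'
#' Bundles every tunable of the pipeline: binding threshold, concentration
#' ratios, pool size, smoothing and analysis-window settings, instrument
#' profile, root seed and I/O paths. Serializes losslessly to YAML; a short
#' content hash of the serialized form is embedded in every output file for
#' provenance.
#'
#' @slot threshold Binding threshold, degC.
#' @slot ratioStandard,ratioFattyAcid Ligand:protein concentration ratios.
#' @slot proteinConcs Permitted protein concentrations, uM.
#' @slot poolMaxSize Maximum ligand-pool size.
#' @slot smoothWindow Savitzky-Golay window in points (0 = automatic, about
#'   1 degC of points).
#' @slot polyorder Smoothing polynomial order.
#' @slot trimFrac Analysis-window trim fraction per temperature extreme.
#' @slot amplitudeK Minimum transition amplitude for a confident Tm call.
#' @slot profileName Instrument profile preset name.
#' @slot rootSeed Root seed for all randomness.
#' @slot paths Named list of I/O paths.
#' @export
setClass("RunConfig",
  representation(threshold = "numeric", ratioStandard = "numeric",
                 ratioFattyAcid = "numeric", proteinConcs = "numeric",
                 poolMaxSize = "integer", smoothWindow = "integer",
                 polyorder = "integer", trimFrac = "numeric",
                 amplitudeK = "numeric", profileName = "character",
                 rootSeed = "integer", paths = "list"))

setValidity("RunConfig", function(object) {
  num <- c(object@threshold, object@ratioStandard, object@ratioFattyAcid,
           object@proteinConcs, object@poolMaxSize, object@polyorder,
           object@trimFrac, object@amplitudeK)
  if (!all(is.finite(num)) || any(num <= 0))
    return("all numeric settings must be positive")
  if (object@smoothWindow < 0) return("smoothWindow must be >= 0 (0 = auto)")
  if (object@trimFrac >= 0.5) return("trimFrac must be < 0.5")
  TRUE
})

#' @describeIn RunConfig Constructor with pipeline defaults.
#' @param threshold,ratioStandard,ratioFattyAcid,proteinConcs,poolMaxSize
#'   See slots.
#' @param smoothWindow,polyorder,trimFrac,amplitudeK,profileName,rootSeed,paths
#'   See slots.
#' @export
runConfig <- function(threshold = 2.0, ratioStandard = 100,
                      ratioFattyAcid = 10, proteinConcs = c(4, 5, 10),
                      poolMaxSize = 10L, smoothWindow = 0L, polyorder = 3L,
                      trimFrac = 0.10, amplitudeK = 5, profileName = "lightcycler480",
                      rootSeed = 1L, paths = list()) {
  new("RunConfig", threshold = as.numeric(threshold),
      ratioStandard = as.numeric(ratioStandard),
      ratioFattyAcid = as.numeric(ratioFattyAcid),
      proteinConcs = as.numeric(proteinConcs),
      poolMaxSize = as.integer(poolMaxSize),
      smoothWindow = as.integer(smoothWindow),
      polyorder = as.integer(polyorder), trimFrac = as.numeric(trimFrac),
      amplitudeK = as.numeric(amplitudeK),
      profileName = as.character(profileName),
      rootSeed = as.integer(rootSeed), paths = paths)
}

.configSlots <- c("threshold", "ratioStandard", "ratioFattyAcid",
                  "proteinConcs", "poolMaxSize", "smoothWindow", "polyorder",
                  "trimFrac", "amplitudeK", "profileName", "rootSeed",
                  "paths")

#' @describeIn RunConfig Convert to a plain list (YAML-ready).
#' @param config A \code{RunConfig}.
#' @export
configAsList <- function(config) {
  out <- lapply(.configSlots, function(s) slot(config, s))
  names(out) <- .configSlots
  out
}

#' @describeIn RunConfig Write to YAML.
#' @param path File path.
#' @export
writeRunConfig <- function(config, path) {
  validObject(config)
  yaml::write_yaml(configAsList(config), path)
  invisible(path)
}

#' @describeIn RunConfig Read back from YAML (lossless round trip).
#' @export
readRunConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals$paths)) vals$paths <- list()
  do.call(runConfig, vals)
}

#' @describeIn RunConfig Short provenance hash of the serialized config
#'   (polynomial hash over the YAML text, hex-encoded).
#' @export
configHash <- function(config) {
  txt <- yaml::as.yaml(configAsList(config))
  h <- 0
  for (b in utf8ToInt(txt)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

setMethod("show", "RunConfig", function(object) {
  cat("RunConfig [", configHash(object), "]: threshold ", object@threshold,
      " degC, ratios ", object@ratioStandard, "x/", object@ratioFattyAcid,
      "x, pools <= ", object@poolMaxSize, ", profile ", object@profileName,
      ", seed ", object@rootSeed, "\n", sep = "")
})
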