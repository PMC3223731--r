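## Per-well RNG substreams: each well's noise depends only on the root seed
## and its well key, so simulation order never matters. 2^31 - 1 keeps the
## derived seed a valid 32-bit integer.
.MOD31 <- 2147483647

.wellSeed <- function(rootSeed, key) {
  h <- 0
  for (b in utf8ToInt(key)) h <- (h * 31 + b) %% .MOD31
  as.integer((as.numeric(rootSeed) + h) %% .MOD31)
}

## Additive fluorescence from dye-ligand interaction of hydrophobic (fatty
## acid) ligands: scales with ligand concentration and fades as temperature
## rises. At the standard 100x concentrations this background rivals the
## protein signal, which is why such ligands are run at 10x.
.fattyAcidBackground <- function(temp, ligandConc, tempStart) {
  20 * ligandConc * (0.6 + 0.4 * exp(-(temp - tempStart) / 30))
}

## Protein-free wells: a weak dye/buffer background with no melt transition.
.backgroundTrace <- function(temp, role, tempStart) {
  base <- if (role == "dye_only") 120 else 40
  base * exp(-(temp - tempStart) / 40) + 30
}

#' Render one simulated melt curve
#'
#' Generates a SYPRO-orange-style melt trace on the instrument grid:
#' \deqn{F(T) = (1-f) N(T) + f\,U(T) e^{-k \max(0, T - T_m')} + bg(T) + \epsilon}
#' where \eqn{f} is the two-state unfolded fraction centred on the apparent
#' midpoint \eqn{T_m'} (ligand-shifted midpoint plus the instrument's
#' systematic offset), \eqn{N} and \eqn{U} are the linear baselines, \eqn{k}
#' the post-transition decay, \eqn{bg} an optional fatty-acid dye background,
#' and \eqn{\epsilon} additive Gaussian noise.
#'
#' @param params \code{\link{thermoParams}} for the protein.
#' @param kd Ground-truth dissociation constant, uM (\code{Inf} = no binding).
#' @param ligandConc Ligand concentration, uM.
#' @param profile \code{\link{instrumentProfile}} defining grid, offset, noise.
#' @param fattyAcid Logical; add the high hydrophobic-ligand dye background.
#' @param seed Root seed; combined with \code{wellKey} into a per-well
#'   substream. \code{NULL} renders noise-free.
#' @param wellKey Identifier entering the per-well noise substream.
#' @return List: \code{temperature}, \code{fluorescence}, \code{tmApparent}
#'   (degC, including instrument offset), \code{tmTrue} (offset-free),
#'   \code{saturated}.
#' @examples
#' cv <- renderCurve(thermoParams(), profile = instrumentProfile())
#' length(cv$temperature)   # 2101 points: 30/degC over 70 degC
#' @export
renderCurve <- function(params, kd = Inf, ligandConc = 0,
                        profile = instrumentProfile(), fattyAcid = FALSE,
                        seed = NULL, wellKey = "W1") {
  stopifnot(is(params, "ThermoParams"), is(profile, "InstrumentProfile"))
  validObject(params); validObject(profile)
  temp <- temperatureGrid(profile)
  win <- range(temp)
  if (params@tm0 < win[1] || params@tm0 > win[2])
    stop("tm0 lies outside the acquisition window")
  sh <- shiftedTm(params, kd, ligandConc, window = win)
  tmApp <- sh$tm + profile@tmOffset
  shiftedParams <- params
  shiftedParams@tm0 <- min(max(tmApp, win[1]), win[2])
  f <- fractionUnfolded(temp, shiftedParams)
  nat <- params@nativeBaseline[1] + params@nativeBaseline[2] * temp
  unf <- params@unfoldedBaseline[1] + params@unfoldedBaseline[2] * temp
  decay <- exp(-params@postPeakDecay * pmax(0, temp - shiftedParams@tm0))
  fl <- (1 - f) * nat + f * unf * decay
  if (fattyAcid)
    fl <- fl + .fattyAcidBackground(temp, ligandConc, profile@tempStart)
  if (!is.null(seed) && profile@noiseSD > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(.wellSeed(seed, wellKey))
    fl <- fl + stats::rnorm(length(fl), 0, profile@noiseSD)
  }
  list(temperature = temp, fluorescence = fl, tmApparent = shiftedParams@tm0,
       tmTrue = sh$tm, saturated = sh$saturated)
}

#' Simulate all wells of a screening plan
#'
#' Renders one melt curve per planned reaction well. Sample wells look up the
#' ground-truth dissociation constant for their (protein, ligand) pair; pairs
#' absent from \code{truths} do not bind. Pooled wells are rendered with the
#' member ligand giving the largest individual shift (one stabilizer
#' dominates the pool signal). Protein-only controls melt at the protein's
#' reference midpoint; buffer-only and dye-only wells carry only dye/buffer
#' background. Replicate wells draw independent noise; with a fixed seed the
#' result is bit-identical and independent of well order.
#'
#' @param plan A \code{\link{ScreenPlan}}.
#' @param truths data.frame of ground truth: columns \code{protein},
#'   \code{ligand}, \code{kd} (uM), optional \code{bindsNative} (default TRUE;
#'   rows with FALSE are ignored, only native-state binders stabilize).
#' @param params Named list of \code{\link{thermoParams}}, keyed by protein id.
#' @param profile \code{\link{instrumentProfile}}.
#' @param ligandLibrary Ligand library data.frame (needed to flag fatty-acid
#'   wells); may be \code{NULL} when the plan has no ligand content.
#' @param pools Pool membership data.frame (\code{poolId}, \code{ligandId});
#'   required when the plan contains pooled wells.
#' @param seed Root seed for the plate (integer).
#' @return A \code{\link{MeltCurveSet}} with ground truth in
#'   \code{metadata(x)$groundTruth}.
#' @export
simulatePlate <- function(plan, truths, params, profile = instrumentProfile(),
                          ligandLibrary = NULL, pools = NULL, seed = 1) {
  stopifnot(is(plan, "ScreenPlan"))
  validObject(plan)
  w <- planWells(plan)
  if (!nrow(w)) {
    m <- matrix(numeric(0), nrow = length(temperatureGrid(profile)), ncol = 0)
    colnames(m) <- character(0)
    return(MeltCurveSet(m, temperatureGrid(profile), profile = profile,
                        seed = seed))
  }
  truths <- .normalizeTruths(truths)
  needProt <- unique(w$protein[w$role %in% c("sample", "protein_only")])
  missing <- setdiff(needProt, names(params))
  if (length(missing))
    stop("plan references unknown protein(s): ", paste(missing, collapse = ", "))
  if (any(w$contentType == "pool") && is.null(pools))
    stop("plan contains pooled wells; 'pools' membership table required")
  if (!is.null(ligandLibrary)) {
    planned <- unique(c(w$content[w$contentType == "ligand"],
                        if (!is.null(pools)) pools$ligandId))
    unknown <- setdiff(planned, ligandLibrary$ligandId)
    if (length(unknown))
      stop("plan references unknown ligand(s): ", paste(unknown, collapse = ", "))
  }
  faLigands <- if (!is.null(ligandLibrary))
    ligandLibrary$ligandId[ligandLibrary$category == "fatty_acid"] else character(0)

  kdOf <- function(protein, ligand) {
    hit <- truths$protein == protein & truths$ligand == ligand & truths$bindsNative
    if (any(hit)) min(truths$kd[hit]) else Inf
  }
  temp <- temperatureGrid(profile)
  keys <- paste(w$plate, w$well, sep = ":")
  mat <- matrix(NA_real_, nrow = length(temp), ncol = nrow(w),
                dimnames = list(NULL, keys))
  gt <- data.frame(plate = w$plate, well = w$well, key = keys,
                   protein = w$protein, content = w$content,
                   dominantLigand = NA_character_, tmTrue = NA_real_,
                   tmApparent = NA_real_, saturated = FALSE,
                   stringsAsFactors = FALSE)
  for (i in seq_len(nrow(w))) {
    role <- w$role[i]
    if (role %in% c("buffer_only", "dye_only")) {
      bg <- .backgroundTrace(temp, role, profile@tempStart)
      s <- .wellSeed(seed, keys[i])
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      set.seed(s)
      mat[, i] <- bg + stats::rnorm(length(temp), 0, profile@noiseSD)
      if (!is.null(old)) assign(".Random.seed", old, globalenv())
      next
    }
    p <- params[[w$protein[i]]]
    kd <- Inf; conc <- 0; dom <- NA_character_; fa <- FALSE
    if (role == "sample") {
      conc <- w$ligandConc[i]
      if (w$contentType[i] == "ligand") {
        kd <- kdOf(w$protein[i], w$content[i])
        dom <- w$content[i]
        fa <- w$content[i] %in% faLigands
      } else if (w$contentType[i] == "pool") {
        members <- pools$ligandId[pools$poolId == w$content[i]]
        if (!length(members))
          stop("pool id absent from pools table: ", w$content[i])
        shifts <- vapply(members, function(lg)
          shiftedTm(p, kdOf(w$protein[i], lg), conc, range(temp))$tm,
          numeric(1))
        dom <- members[which.max(shifts)]
        kd <- kdOf(w$protein[i], dom)
        fa <- any(members %in% faLigands)
      }
    }
    cv <- renderCurve(p, kd = kd, ligandConc = conc, profile = profile,
                      fattyAcid = fa, seed = seed, wellKey = keys[i])
    mat[, i] <- cv$fluorescence
    gt$dominantLigand[i] <- dom
    gt$tmTrue[i] <- cv$tmTrue
    gt$tmApparent[i] <- cv$tmApparent
    gt$saturated[i] <- cv$saturated
  }
  wd <- w
  rownames(wd) <- keys
  MeltCurveSet(mat, temp, wellData = wd, profile = profile, seed = seed,
               stage = planStage(plan), groundTruth = gt)
}

.normalizeTruths <- function(truths) {
  if (is.null(truths) || !nrow(truths))
    return(data.frame(protein = character(0), ligand = character(0),
                      kd = numeric(0), bindsNative = logical(0)))
  stopifnot(all(c("protein", "ligand", "kd") %in% colnames(truths)))
  if (any(!is.na(truths$kd) & truths$kd <= 0)) stop("kd must be > 0")
  if (is.null(truths$bindsNative)) truths$bindsNative <- TRUE
  truths
}
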