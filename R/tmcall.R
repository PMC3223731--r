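.validateCurve <- function(temperature, fluorescence, minPoints = 50L) {
  if (length(temperature) != length(fluorescence))
    stop("temperature and fluorescence must have equal length")
  if (length(temperature) < minPoints)
    stop("melt curve needs at least ", minPoints, " points")
  if (!all(is.finite(temperature)) || any(diff(temperature) <= 0))
    stop("temperatures must be finite and strictly increasing")
  if (!all(is.finite(fluorescence)))
    stop("fluorescence values must be finite")
  invisible(TRUE)
}

## Default smoothing window: about one degree's worth of points, forced odd
## and wide enough for the cubic fit.
.defaultWindow <- function(temperature, polyorder = 3L) {
  ppd <- 1 / stats::median(diff(temperature))
  n <- max(polyorder + 2L, round(ppd) + 1L)
  n <- min(n, length(temperature) - 2L)
  if (n %% 2L == 0L) n <- n + 1L
  as.integer(n)
}

#' Savitzky-Golay smoothing of a melt curve
#'
#' Local polynomial smoothing preserves the position of derivative extrema,
#' which is what the Tm call rests on. A polynomial of order
#' \code{polyorder} is fit over a sliding window; traces that are themselves
#' polynomials up to that order are reproduced exactly.
#'
#' @param temperature,fluorescence Numeric vectors of equal length;
#'   temperatures strictly increasing on a (near-)uniform grid.
#' @param window Odd window length in points; default spans about 1 degC.
#' @param polyorder Polynomial order (< window), default 3.
#' @return Smoothed fluorescence vector on the same grid.
#' @export
smoothCurve <- function(temperature, fluorescence, window = NULL,
                        polyorder = 3L) {
  .validateCurve(temperature, fluorescence, minPoints = 5L)
  if (is.null(window)) window <- .defaultWindow(temperature, polyorder)
  window <- as.integer(window)
  if (window %% 2L == 0L) stop("window must be odd")
  if (window >= length(fluorescence)) stop("window must be < curve length")
  if (polyorder >= window) stop("polyorder must be < window")
  as.numeric(signal::sgolayfilt(fluorescence, p = polyorder, n = window))
}

#' Negative first-derivative curve
#'
#' Computes \eqn{-(dF/dT)} by central differences on the interior grid (one
#' point trimmed at each edge). Rising fluorescence (unfolding) yields
#' negative values, so the melting midpoint appears as the curve minimum --
#' the convention of qPCR instrument "Tm calling" displays.
#'
#' @param temperature,fluorescence Equal-length numeric vectors (fluorescence
#'   is typically smoothed first).
#' @return data.frame with \code{temperature} and \code{negDFDT} on the
#'   interior grid.
#' @export
negDerivative <- function(temperature, fluorescence) {
  .validateCurve(temperature, fluorescence, minPoints = 3L)
  n <- length(temperature)
  i <- 2:(n - 1)
  d <- (fluorescence[i + 1] - fluorescence[i - 1]) /
       (temperature[i + 1] - temperature[i - 1])
  data.frame(temperature = temperature[i], negDFDT = -d)
}

#' Call the melting midpoint from one melt curve
#'
#' The curve is smoothed, differentiated, and the melting midpoint taken as
#' the temperature of the global minimum of \eqn{-(dF/dT)} inside the
#' analysis window. The window trims \code{trimFrac} of the temperature range
#' at each extreme and additionally excludes the leading dye-background
#' descent: the search starts at the minimum of smoothed fluorescence over
#' the first half of the trimmed window, so an initial high-fluorescence
#' decay is never mistaken for the transition.
#'
#' Quality control: the transition amplitude is the depth of the derivative
#' minimum relative to the median absolute fluctuation of the derivative
#' outside the peak region; curves whose amplitude falls below
#' \code{amplitudeK} are flagged \code{no_clear_melt} (no midpoint reported).
#' An extremum touching the window boundary is flagged \code{edge_of_window}.
#' Ties are broken toward the lowest temperature. Secondary derivative minima
#' at least half as deep as the main one are counted in \code{secondary}.
#'
#' @param temperature,fluorescence The raw melt trace (>= 50 points,
#'   strictly increasing temperatures).
#' @param window Smoothing window (odd, points); default about 1 degC.
#' @param polyorder Smoothing polynomial order.
#' @param trimFrac Fraction of the temperature range trimmed at each end.
#' @param amplitudeK Minimum transition amplitude (peak depth over baseline
#'   fluctuation) for a confident call.
#' @return One-row data.frame: \code{tm}, \code{extremum}, \code{amplitude},
#'   \code{flag} (ok / no_clear_melt / edge_of_window), \code{secondary}.
#' @examples
#' cv <- renderCurve(thermoParams(), profile = instrumentProfile())
#' callTm(cv$temperature, cv$fluorescence)
#' @export
callTm <- function(temperature, fluorescence, window = NULL, polyorder = 3L,
                   trimFrac = 0.10, amplitudeK = 5) {
  .validateCurve(temperature, fluorescence)
  sm <- smoothCurve(temperature, fluorescence, window = window,
                    polyorder = polyorder)
  dv <- negDerivative(temperature, sm)
  ## central differences re-amplify residual high-frequency noise at dense
  ## sampling; the derivative trace itself varies over several degrees, so it
  ## tolerates a wider (~2 degC) local-polynomial smoothing pass before
  ## extremum selection
  dwin <- min(2L * .defaultWindow(dv$temperature, polyorder) - 1L,
              nrow(dv) - 2L)
  if (dwin %% 2L == 0L) dwin <- dwin - 1L
  if (dwin > polyorder + 1L)
    dv$negDFDT <- smoothCurve(dv$temperature, dv$negDFDT, window = dwin,
                              polyorder = polyorder)
  tlo <- min(temperature) + trimFrac * diff(range(temperature))
  thi <- max(temperature) - trimFrac * diff(range(temperature))
  keep <- which(dv$temperature >= tlo & dv$temperature <= thi)
  dv <- dv[keep, ]
  smw <- sm[keep + 1L]                     # smoothed values on the same rows
  ## exclude the leading monotone dye-background descent: start at the
  ## fluorescence minimum over the first half of the window
  half <- seq_len(max(1L, floor(nrow(dv) / 2)))
  start <- half[which.min(smw[half])]
  dv <- dv[start:nrow(dv), , drop = FALSE]

  noCall <- data.frame(tm = NA_real_, extremum = NA_real_,
                       amplitude = 0, flag = "no_clear_melt", secondary = 0L,
                       stringsAsFactors = FALSE)
  if (!nrow(dv)) return(noCall)
  imin <- which.min(dv$negDFDT)            # first index wins ties: lowest T
  tm <- dv$temperature[imin]
  ext <- dv$negDFDT[imin]
  ## baseline fluctuation sampled from the outer 15% of the analysis window,
  ## which stays outside the transition whatever its width
  nn <- nrow(dv)
  k15 <- max(3L, ceiling(0.15 * nn))
  baseIdx <- unique(c(seq_len(min(k15, nn)), seq.int(max(1L, nn - k15 + 1L), nn)))
  baseIdx <- baseIdx[abs(dv$temperature[baseIdx] - tm) > 1]
  base <- dv$negDFDT[baseIdx]
  if (length(base) < 3L) base <- dv$negDFDT
  fluct <- stats::median(abs(base - stats::median(base)))
  depth <- stats::median(base) - ext
  amp <- if (depth <= 0) 0 else depth / max(fluct, .Machine$double.eps * max(1, abs(ext)))
  if (amp < amplitudeK) {
    noCall$amplitude <- amp
    return(noCall)
  }
  flag <- if (imin == 1L || imin == nrow(dv)) "edge_of_window" else "ok"
  if (flag == "ok") {
    ## parabolic sub-grid refinement of the extremum (standard peak
    ## interpolation); confined to +/- half a grid step
    y0 <- dv$negDFDT[imin - 1L]; y1 <- dv$negDFDT[imin]; y2 <- dv$negDFDT[imin + 1L]
    den <- y0 - 2 * y1 + y2
    if (den > 0) {
      delta <- 0.5 * (y0 - y2) / den
      delta <- max(-0.5, min(0.5, delta))
      step <- dv$temperature[imin + 1L] - dv$temperature[imin]
      tm <- tm + delta * step
    }
  }
  ## secondary transitions: local minima at least half the main depth,
  ## outside +/- 1 degC of the main peak
  y <- dv$negDFDT
  loc <- which(diff(sign(diff(y))) > 0) + 1L
  sec <- sum(abs(dv$temperature[loc] - tm) > 1 &
             (stats::median(base) - y[loc]) >= depth / 2)
  data.frame(tm = tm, extremum = ext, amplitude = amp, flag = flag,
             secondary = as.integer(sec), stringsAsFactors = FALSE)
}

#' Call Tm for every well of a MeltCurveSet
#'
#' @param x A \code{\link{MeltCurveSet}}.
#' @param ... Passed to \code{\link{callTm}}.
#' @return data.frame with one row per well: well metadata key columns
#'   (plate, well, protein, content, role, replicate, solvent when present)
#'   plus \code{tm}, \code{extremum}, \code{amplitude}, \code{flag},
#'   \code{secondary}.
#' @export
callTmSet <- function(x, ...) {
  stopifnot(is(x, "MeltCurveSet"))
  temp <- temperatures(x)
  fl <- fluorescence(x)
  res <- do.call(rbind, lapply(seq_len(ncol(fl)), function(i)
    callTm(temp, fl[, i], ...)))
  wd <- wellData(x)
  keep <- intersect(c("plate", "well", "protein", "contentType", "content",
                      "solvent", "replicate", "role"), colnames(wd))
  out <- cbind(key = colnames(fl), wd[, keep, drop = FALSE], res)
  rownames(out) <- NULL
  out
}
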