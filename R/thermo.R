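## Gas constant, J/(mol K). Temperatures are degC everywhere at the surface;
## conversion to Kelvin is confined to this file.
.RGAS <- 8.314
.C2K <- 273.15

#' Equilibrium fraction unfolded under the two-state model
#'
#' Two-state van 't Hoff unfolding without a heat-capacity term:
#' \deqn{f(T) = 1 / (1 + \exp(\Delta G(T) / (R T)))}
#' with \eqn{\Delta G(T) = \Delta H_{vH} (1 - T / T_m)} (temperatures in
#' Kelvin internally). At \code{tm0} the fraction is exactly 1/2 and \code{f}
#' is monotone nondecreasing in temperature.
#'
#' @param temp Temperature(s), degC.
#' @param params A \code{\link{thermoParams}} object.
#' @return Numeric vector of unfolded fractions in [0, 1].
#' @examples
#' fractionUnfolded(55, thermoParams(tm0 = 55))   # 0.5
#' @export
fractionUnfolded <- function(temp, params) {
  stopifnot(is(params, "ThermoParams"))
  validObject(params)
  temp <- as.numeric(temp)
  if (!all(is.finite(temp))) stop("temperatures must be finite")
  tK <- temp + .C2K
  if (any(tK <= 0)) stop("temperature below absolute zero")
  tmK <- params@tm0 + .C2K
  dG <- params@dhVH * 1000 * (1 - tK / tmK)      # J/mol
  1 / (1 + exp(dG / (.RGAS * tK)))
}

#' Ligand-shifted melting midpoint
#'
#' A ligand that binds the native state with dissociation constant \code{kd}
#' raises the apparent unfolding free energy by \eqn{R T \log(1 + L / K_d)}
#' (ligand in excess, so free ligand is approximated by total ligand). The
#' shifted midpoint solves
#' \deqn{\Delta G_{unfold}(T) + R T \log(1 + L/K_d) = 0, \quad T \ge tm_0}
#' by bracketed root finding on the acquisition window. When the stabilization
#' is so large that no root lies inside the window, the window edge is
#' returned with \code{saturated = TRUE}.
#'
#' @param params A \code{\link{thermoParams}} object.
#' @param kd Dissociation constant, uM (> 0). \code{Inf} means no binding.
#' @param ligandConc Total ligand concentration, uM (>= 0).
#' @param window Numeric length 2, acquisition window in degC; the default is
#'   the LightCycler-like ramp.
#' @return List with \code{tm} (degC) and \code{saturated} (logical).
#' @examples
#' p <- thermoParams(tm0 = 55, dhVH = 450)
#' shiftedTm(p, kd = 10, ligandConc = 1000)$tm - 55   # the delta-Tm
#' @export
shiftedTm <- function(params, kd, ligandConc, window = c(25, 95)) {
  stopifnot(is(params, "ThermoParams"))
  validObject(params)
  if (!is.numeric(ligandConc) || length(ligandConc) != 1L || ligandConc < 0 ||
      !is.finite(ligandConc))
    stop("ligandConc must be a finite scalar >= 0")
  if (!is.numeric(kd) || length(kd) != 1L || is.na(kd) || kd <= 0)
    stop("kd must be a scalar > 0 (Inf for no binding)")
  if (ligandConc == 0 || is.infinite(kd))
    return(list(tm = params@tm0, saturated = FALSE))
  stab <- log1p(ligandConc / kd)
  tmK <- params@tm0 + .C2K
  dH <- params@dhVH * 1000
  ## f(T) > 0 below the shifted midpoint, < 0 above it
  f <- function(tC) {
    tK <- tC + .C2K
    dH * (1 - tK / tmK) + .RGAS * tK * stab
  }
  hi <- max(window)
  if (f(hi) > 0)
    return(list(tm = hi, saturated = TRUE))
  root <- stats::uniroot(f, lower = params@tm0, upper = hi, tol = 1e-9)
  list(tm = root$root, saturated = FALSE)
}

#' Dissociation constant producing a target midpoint shift
#'
#' Inverts the shifted-midpoint relation: returns the \code{kd} (uM) at which
#' \code{ligandConc} uM of ligand raises the midpoint by exactly
#' \code{deltaTm} degC. Useful for planting ground-truth binders with
#' prescribed delta-Tm in simulations.
#'
#' @param params A \code{\link{thermoParams}} object.
#' @param deltaTm Target midpoint shift, degC (> 0).
#' @param ligandConc Ligand concentration at which the shift is realized, uM.
#' @return Dissociation constant, uM.
#' @examples
#' p <- thermoParams()
#' kd <- kdForShift(p, deltaTm = 17, ligandConc = 1000)
#' shiftedTm(p, kd, 1000)$tm - tm0(p)   # 17
#' @export
kdForShift <- function(params, deltaTm, ligandConc) {
  stopifnot(is(params, "ThermoParams"), deltaTm > 0, ligandConc > 0)
  tmK <- params@tm0 + .C2K
  tK <- params@tm0 + deltaTm + .C2K
  dH <- params@dhVH * 1000
  x <- (dH / .RGAS) * (1 / tmK - 1 / tK)   # required log(1 + L/kd)
  ligandConc / expm1(x)
}
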