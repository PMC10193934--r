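#' Helical geometry parameters for the twist-to-groove relation
#'
#' Parameters of the geometric construction relating the twist angle to
#' the major groove width of an A-form duplex: walking along one backbone
#' strand for `strand_azimuth/omega` base-pair steps and crossing to the
#' complementary strand spans the same vertical distance as the groove
#' width plus the inclined diameter, giving
#' \deqn{G \approx h\,\beta/\omega - D \sin\theta.}
#'
#' @param rise Helical rise `h`, nm per bp.  Default `NULL` calibrates the
#'   rise so that the relation passes through the equilibrium point
#'   (32.15 deg, 0.52 nm) of the reference groove-width ensemble, giving
#'   h of about 0.247 nm.
#' @param diameter Duplex diameter `D`, nm (default 1.95).
#' @param inclination Base-pair inclination `theta`, degrees, in (0, 90)
#'   (default 16.5, midpoint of the 15.5-17.5 range).
#' @param strand_azimuth Azimuthal angle `beta` between the two strands,
#'   degrees (default 140).
#' @return An object of class `geometry_params`.
#' @export
geometry_params <- function(rise = NULL, diameter = 1.95, inclination = 16.5,
                            strand_azimuth = 140) {
  if (diameter <= 0 || strand_azimuth <= 0)
    stop("'diameter' and 'strand_azimuth' must be positive")
  if (inclination <= 0 || inclination >= 90)
    stop("'inclination' must lie in (0, 90) degrees")
  p <- structure(list(rise = rise, diameter = diameter,
                      inclination = inclination,
                      strand_azimuth = strand_azimuth),
                 class = "geometry_params")
  if (is.null(rise)) p$rise <- calibrate_rise(32.15, 0.52, p)
  if (p$rise <= 0) stop("'rise' must be positive")
  p
}

#' @export
print.geometry_params <- function(x, ...) {
  cat(sprintf(
    "Helix geometry: h = %.4f nm/bp, D = %.3g nm, theta = %.3g deg, beta = %.4g deg\n",
    x$rise, x$diameter, x$inclination, x$strand_azimuth))
  invisible(x)
}

#' Major groove width predicted from the twist angle
#'
#' Evaluates `G = h * beta / omega - D * sin(theta)`.  Strictly decreasing
#' in the twist: a smaller twist means more base-pair steps span the fixed
#' backbone azimuth, hence a wider groove.
#'
#' @param omega Twist angle(s), degrees per bp step (> 0).
#' @param params A [geometry_params()].
#' @return Groove width(s), nm.
#' @export
#' @examples
#' groove_from_twist(32.15, geometry_params(rise = 0.28))  # ~0.666 nm
groove_from_twist <- function(omega, params = geometry_params()) {
  if (any(!is.finite(omega)) || any(omega <= 0))
    stop("'omega' must be positive (degrees)")
  params$rise * params$strand_azimuth / omega -
    params$diameter * sin(params$inclination * pi / 180)
}

#' Calibrate the helical rise from an equilibrium point
#'
#' Solves the geometric relation for the rise `h` such that
#' `groove_from_twist(omega0)` equals `conj0`:
#' `h = (conj0 + D sin(theta)) * omega0 / beta`.
#'
#' @param omega0 Equilibrium twist, degrees (> 0).
#' @param conj0 Equilibrium groove width, nm.
#' @param params A [geometry_params()] (its `rise` is ignored).
#' @return Calibrated rise, nm per bp.
#' @export
#' @examples
#' calibrate_rise(32.15, 0.52)  # ~0.2466 nm
calibrate_rise <- function(omega0, conj0, params = NULL) {
  if (omega0 <= 0) stop("'omega0' must be positive")
  D <- if (is.null(params)) 1.95 else params$diameter
  th <- if (is.null(params)) 16.5 else params$inclination
  beta <- if (is.null(params)) 140 else params$strand_azimuth
  (conj0 + D * sin(th * pi / 180)) * omega0 / beta
}
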