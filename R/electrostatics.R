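#' Electrostatic driver parameters
#'
#' Parameters of the screened phosphate-phosphate repulsion model: the P-P
#' distance `r` across the major groove, the dimensionless rescale factor
#' `alpha` absorbing the many-pair and other approximations of the
#' single-pair estimate, and the physical context.  `r` is held fixed as
#' the salt concentration varies (the single-pair model deliberately
#' ignores the weak dependence of `r` on salt).
#'
#' @param pp_distance Phosphate-phosphate distance, nm (default 0.6).
#' @param rescale_alpha Dimensionless force rescale factor (default 1.8).
#'   Applied downstream in [salt_twist_curve()], never inside [pp_force()].
#' @param context A [physical_context()].
#' @return An object of class `electrostatic_params`.
#' @export
electrostatic_params <- function(pp_distance = 0.6, rescale_alpha = 1.8,
                                 context = physical_context()) {
  if (pp_distance <= 0) stop("'pp_distance' must be positive")
  if (rescale_alpha <= 0) stop("'rescale_alpha' must be positive")
  structure(list(pp_distance = pp_distance, rescale_alpha = rescale_alpha,
                 context = context),
            class = "electrostatic_params")
}

#' Debye screening length of a monovalent salt solution
#'
#' @param c_salt Salt concentration, molar.
#' @return Debye length in nm, `0.3034 / sqrt(c_salt)`.
#' @export
#' @examples
#' debye_length(1)     # 0.3034 nm
#' debye_length(0.01)  # 3.034 nm
debye_length <- function(c_salt) {
  if (any(!is.finite(c_salt)) || any(c_salt <= 0))
    stop("'c_salt' must be positive (molar)")
  0.3034 / sqrt(c_salt)
}

#' Screened phosphate-phosphate repulsive force
#'
#' Magnitude of the Debye-screened Coulomb force between two unit charges a
#' distance `r` apart,
#' \deqn{f = \frac{e^2}{4\pi\epsilon_r\epsilon_0}
#'       e^{-r/\lambda_D}\left(\frac{1}{r^2} + \frac{1}{r\lambda_D}\right),}
#' the derivative of the screened interaction potential
#' \eqn{e^2 e^{-r/\lambda_D}/(4\pi\epsilon_r\epsilon_0 r)} with respect to
#' `r`.  This is the single-pair estimate of the force that widens the
#' major groove when screening weakens at low salt.
#'
#' @param c_salt Salt concentration, molar.
#' @param params An [electrostatic_params()].
#' @return Force in kBT/nm at the context temperature.
#' @export
#' @examples
#' pp_force(1)  # ~0.83 kBT/nm
pp_force <- function(c_salt, params = electrostatic_params()) {
  if (any(!is.finite(c_salt)) || any(c_salt <= 0))
    stop("'c_salt' must be positive (molar)")
  r <- params$pp_distance
  if (r <= 0) stop("'pp_distance' must be positive")
  lam <- debye_length(c_salt)
  pref_J_nm <- .const$e^2 /
    (4 * pi * params$context$dielectric_constant * .const$eps0) * 1e9
  f_J_per_nm <- pref_J_nm * exp(-r / lam) * (1 / r^2 + 1 / (r * lam))
  f_J_per_nm / kbt_energy(params$context$temperature)$joules
}

#' Salt-induced change of the groove-widening force
#'
#' `pp_force(c_salt) - pp_force(reference_salt)`: positive when screening
#' is weaker than at the reference concentration, i.e. the net force widens
#' the major groove as salt is lowered.  The rescale factor `alpha` is not
#' applied here; it multiplies the force in the linear-response step.
#'
#' @inheritParams pp_force
#' @return Force change in kBT/nm (zero at the reference concentration).
#' @export
delta_force_salt <- function(c_salt, params = electrostatic_params()) {
  pp_force(c_salt, params) - pp_force(params$context$reference_salt, params)
}
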