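#' Equilibrium deformation under a generalized force
#'
#' Minimizing the tilted per-bp energy
#' \deqn{P = \tfrac12 k_\omega \Delta\omega^2 + \tfrac12 k_X \Delta X^2 +
#'   k_{\omega X} \Delta\omega \Delta X - \Delta f\, \Delta X}
#' gives the closed-form linear response
#' \deqn{\Delta\omega = \frac{-k_{\omega X}\,\Delta f}
#'         {k_\omega k_X - k_{\omega X}^2}, \qquad
#'       \Delta X = \frac{k_\omega\,\Delta f}
#'         {k_\omega k_X - k_{\omega X}^2}.}
#' A positive force widens the conjugate coordinate and, for positive
#' cross-coupling, reduces the twist.
#'
#' @param constants A positive-definite [coupling_constants()].
#' @param delta_f Generalized force on the conjugate coordinate, kBT/nm.
#' @return Named numeric `c(delta_twist = deg, delta_conj = nm)`.
#' @export
#' @examples
#' equilibrium_shift(coupling_preset("rna-eq3"), 1)
equilibrium_shift <- function(constants, delta_f) {
  if (!inherits(constants, "coupling_constants"))
    stop("'constants' must be a coupling_constants object")
  d <- constants$k_omega * constants$k_conj - constants$k_cross^2
  c(delta_twist = -constants$k_cross * delta_f / d,
    delta_conj  =  constants$k_omega * delta_f / d)
}

#' Brute-force grid minimization of the tilted harmonic energy
#'
#' Independent numerical check of [equilibrium_shift()]: evaluates the
#' tilted energy on a dense rectangular lattice of (twist, conjugate)
#' deviations and returns the arg-min.  Errors if the optimum lands on the
#' grid boundary (grid too small to bracket it).
#'
#' Because the energy valley is tilted with respect to the lattice axes,
#' the arg-min of a single lattice can sit up to a couple of steps away
#' from the continuum optimum along the soft direction; `refine`
#' grid-shrinking passes (each 10x finer, centred on the previous arg-min)
#' push the discretization error well below one initial step.
#'
#' @param constants A [coupling_constants()].
#' @param delta_f Generalized force, kBT/nm.
#' @param grid_halfwidth Half-width of the lattice, length-2 `(deg, nm)`
#'   or a scalar used for both.
#' @param grid_step Initial lattice step, length-2 `(deg, nm)` or scalar.
#' @param refine Number of 10x refinement passes (default 2).
#' @return Named numeric `c(delta_twist, delta_conj)` on the final lattice;
#'   agreement with [equilibrium_shift()] is within one initial grid step.
#' @export
minimize_tilted_oracle <- function(constants, delta_f,
                                   grid_halfwidth = c(2, 1),
                                   grid_step = c(1e-3, 1e-3),
                                   refine = 2) {
  if (!inherits(constants, "coupling_constants"))
    stop("'constants' must be a coupling_constants object")
  hw <- rep_len(as.numeric(grid_halfwidth), 2)
  st <- rep_len(as.numeric(grid_step), 2)
  kw <- constants$k_omega; kc <- constants$k_conj; kx <- constants$k_cross
  argmin_lattice <- function(cx, cy, hw, st, check_boundary) {
    gx <- seq(cx - hw[1], cx + hw[1], by = st[1])
    gy <- seq(cy - hw[2], cy + hw[2], by = st[2])
    # P(x, y) on the lattice as an outer sum of separable pieces
    px <- 0.5 * kw * gx^2
    py <- 0.5 * kc * gy^2 - delta_f * gy
    P <- outer(px, py, `+`) + outer(gx, gy) * kx
    idx <- arrayInd(which.min(P), dim(P))
    if (check_boundary &&
        (idx[1] %in% c(1L, length(gx)) || idx[2] %in% c(1L, length(gy))))
      stop("optimum on grid boundary; enlarge 'grid_halfwidth'")
    c(gx[idx[1]], gy[idx[2]])
  }
  at <- argmin_lattice(0, 0, hw, st, check_boundary = TRUE)
  for (i in seq_len(refine)) {
    hw <- 3 * st
    st <- st / 10
    at <- argmin_lattice(at[1], at[2], hw, st, check_boundary = FALSE)
  }
  c(delta_twist = at[1], delta_conj = at[2])
}

response_curve <- function(data, stimulus_type, constants, driver_params) {
  structure(list(data = data, stimulus_type = stimulus_type,
                 constants = constants, driver_params = driver_params),
            class = "response_curve")
}

#' @export
print.response_curve <- function(x, ...) {
  cat("Response curve (", x$stimulus_type, "), ", nrow(x$data),
      " stimulus values\n", sep = "")
  print(x$data, row.names = FALSE)
  invisible(x)
}

#' @export
plot.response_curve <- function(x, ...) {
  graphics::plot(x$data$stimulus, x$data$delta_twist,
                 xlab = x$stimulus_type, ylab = "delta twist (deg/bp)",
                 log = if (x$stimulus_type == "salt") "x" else "", ...)
  invisible(x)
}

#' Predicted twist change versus salt concentration
#'
#' For each concentration, the screened P-P force change relative to the
#' reference salt is rescaled by `alpha` and fed through the closed-form
#' linear response.  The twist change is zero at the reference
#' concentration and decreases steadily as salt is lowered (for positive
#' cross-coupling).
#'
#' @param constants A [coupling_constants()].
#' @param eparams An [electrostatic_params()] (carries `alpha`, `r`, the
#'   reference salt and the temperature).
#' @param c_list Salt concentrations, molar.
#' @return A `response_curve` whose `data` has columns `stimulus` (M),
#'   `delta_f` (kBT/nm, unscaled), `delta_twist` (deg/bp) and `delta_conj`
#'   (nm).
#' @export
#' @examples
#' salt_twist_curve(coupling_preset("rna-eq3"), electrostatic_params(),
#'                  c(1, 0.5, 0.1, 0.05))
salt_twist_curve <- function(constants, eparams = electrostatic_params(),
                             c_list) {
  if (any(c_list <= 0)) stop("salt concentrations must be positive")
  df <- vapply(c_list, delta_force_salt, numeric(1), params = eparams)
  shifts <- vapply(df, function(f)
    equilibrium_shift(constants, eparams$rescale_alpha * f), numeric(2))
  response_curve(data.frame(stimulus = c_list, delta_f = df,
                            delta_twist = shifts[1, ],
                            delta_conj = shifts[2, ]),
                 "salt", constants,
                 list(alpha = eparams$rescale_alpha,
                      pp_distance = eparams$pp_distance,
                      reference_salt = eparams$context$reference_salt,
                      temperature = eparams$context$temperature))
}

#' Predicted twist change versus temperature change
#'
#' Entropic driver analogue of [salt_twist_curve()]: each temperature
#' offset produces a groove-widening force `k_SG * delta_T` which is fed
#' through the closed-form linear response.
#'
#' @param constants A [coupling_constants()].
#' @param k_SG Entropy slope, kJ/(mol K nm).
#' @param dT_list Temperature offsets from the reference, degrees Celsius.
#' @param temperature Working temperature, kelvin.
#' @return A `response_curve` (stimulus in degrees Celsius offset).
#' @export
temp_twist_curve <- function(constants, k_SG, dT_list, temperature = 295) {
  df <- thermal_force(dT_list, k_SG, temperature)
  shifts <- vapply(df, function(f) equilibrium_shift(constants, f),
                   numeric(2))
  response_curve(data.frame(stimulus = dT_list, delta_f = df,
                            delta_twist = shifts[1, ],
                            delta_conj = shifts[2, ]),
                 "temperature", constants,
                 list(k_SG = k_SG, temperature = temperature))
}

#' Twist change per degree of temperature
#'
#' The linear-response temperature coefficient
#' \deqn{\frac{\Delta\omega}{\Delta T} =
#'   \frac{-k_{\omega X}}{k_\omega k_X - k_{\omega X}^2}\, k_{SG},}
#' with `k_SG` converted to kBT/(nm K) at the working temperature.
#' Negative for positive cross-coupling and positive entropy slope.
#'
#' @param constants A [coupling_constants()].
#' @param k_SG Entropy slope, kJ/(mol K nm).
#' @param temperature Working temperature, kelvin.
#' @return Coefficient in deg/(degC bp).
#' @export
#' @examples
#' temp_twist_coefficient(coupling_preset("rna-eq3"), 0.024)  # ~ -0.009
temp_twist_coefficient <- function(constants, k_SG, temperature = 295) {
  unname(equilibrium_shift(constants,
                           kjmol_to_kbt(k_SG, temperature))["delta_twist"])
}

#' Generic force-tilt response curve
#'
#' Direct application of the closed-form linear response to a list of
#' user-supplied generalized forces (e.g. the groove-width force exerted by
#' a stretching protocol).
#'
#' @param constants A [coupling_constants()].
#' @param f_list Generalized forces on the conjugate coordinate, kBT/nm.
#' @return A `response_curve` (stimulus in kBT/nm).
#' @export
force_twist_curve <- function(constants, f_list) {
  shifts <- vapply(f_list, function(f) equilibrium_shift(constants, f),
                   numeric(2))
  response_curve(data.frame(stimulus = f_list, delta_f = f_list,
                            delta_twist = shifts[1, ],
                            delta_conj = shifts[2, ]),
                 "force", constants, list())
}
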