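#' Specification for a synthetic harmonic ensemble
#'
#' Describes the conditions under which [sample_pair_ensemble()] draws a
#' synthetic helical-parameter ensemble: the per-bp coupling constants, the
#' chain-averaging length, the number of snapshots, the temperature, an
#' optional generalized tilt force on the conjugate coordinate, and a
#' mandatory seed.
#'
#' @param constants A [coupling_constants()] object.
#' @param n_bp Chain-averaging length, base pairs (default 19, the central
#'   window used to avoid duplex end effects).
#' @param n_snapshots Number of snapshots (default 5e4, which gives < 3\%
#'   standard error on recovered constants).
#' @param temperature Kelvin (default 295).
#' @param tilt_force Generalized force on the conjugate coordinate,
#'   kBT/nm; positive widens the coordinate (default 0).
#' @param seed Integer seed; mandatory, no hidden global randomness.
#' @return An object of class `ensemble_spec`.
#' @export
ensemble_spec <- function(constants, n_bp = 19, n_snapshots = 5e4,
                          temperature = 295, tilt_force = 0, seed) {
  if (!inherits(constants, "coupling_constants"))
    stop("'constants' must be a coupling_constants object")
  if (missing(seed) || is.null(seed) || !is.finite(seed))
    stop("'seed' is mandatory for stochastic generation")
  if (n_bp < 1 || n_snapshots < 1)
    stop("'n_bp' and 'n_snapshots' must be >= 1")
  structure(list(constants = constants, n_bp = as.integer(n_bp),
                 n_snapshots = as.integer(n_snapshots),
                 temperature = temperature, tilt_force = tilt_force,
                 seed = as.integer(seed)),
            class = "ensemble_spec")
}

#' Sample a chain-averaged (twist, conjugate-coordinate) ensemble
#'
#' Draws per-base-pair deviations `(d_twist, d_conj)` independently across
#' base pairs and snapshots from the bivariate Gaussian whose precision
#' matrix (in kBT units) is the per-bp stiffness matrix
#' `K = [[k_omega, k_cross], [k_cross, k_conj]]`, shifts them by the
#' closed-form equilibrium displacement `K^{-1} (0, tilt_force)` when a tilt
#' force is applied, averages over `n_bp` base pairs per snapshot, and
#' offsets by the reference point `(omega0, conj0)`.  The chain-averaged
#' sample covariance converges to `K^{-1}/n_bp`.
#'
#' This is the package's stand-in for a molecular-dynamics trajectory
#' analysed into helical parameters: it reproduces the harmonic model's
#' equilibrium statistics exactly, with no anharmonicity, no inter-bp
#' coupling and no time correlation.
#'
#' @param spec An [ensemble_spec()].
#' @return A [helical_ensemble()].
#' @export
#' @examples
#' cc <- coupling_preset("rna-eq3")
#' ens <- sample_pair_ensemble(ensemble_spec(cc, n_snapshots = 1000, seed = 1))
#' summary(ens)
sample_pair_ensemble <- function(spec) {
  if (!inherits(spec, "ensemble_spec")) stop("'spec' must be an ensemble_spec")
  cc <- spec$constants
  K <- stiffness_matrix(cc)
  Sigma <- solve(K)
  U <- chol(Sigma)  # t(U) %*% U == Sigma
  set.seed(spec$seed)
  n_tot <- spec$n_bp * spec$n_snapshots
  Z <- matrix(stats::rnorm(2 * n_tot), n_tot, 2)
  X <- Z %*% U
  shift <- as.numeric(Sigma %*% c(0, spec$tilt_force))
  twist_avg <- .colMeans(X[, 1], spec$n_bp, spec$n_snapshots) + cc$omega0 + shift[1]
  conj_avg  <- .colMeans(X[, 2], spec$n_bp, spec$n_snapshots) + cc$conj0 + shift[2]
  helical_ensemble(twist_avg, conj_avg, n_bp = spec$n_bp,
                   temperature = spec$temperature,
                   coordinate_label = cc$coordinate_label,
                   conditions = list(tilt_force = spec$tilt_force,
                                     seed = spec$seed))
}

#' Generate free-energy profiles F(G; T) at several temperatures
#'
#' Builds one-dimensional free-energy profiles
#' \deqn{F(G; T) = U(G) - T\, S(G), \qquad S(G) = s_{coeff}\, G,}
#' on a common conjugate-coordinate grid, one per temperature, each
#' min-referenced and expressed in kBT of its own temperature.  These
#' emulate the groove-width profiles obtained from simulations run at
#' several temperatures, with a known energy/entropy split, and are the
#' round-trip inputs for [decompose_U_S()].
#'
#' @param u_curve The interaction-energy profile U(G) in kJ/mol: either a
#'   function of G or a two-column data frame (G, U) interpolated onto
#'   `grid`.
#' @param s_coeff Entropy slope dS/dG, kJ/(mol K nm); a 1 degree-Celsius
#'   increment equals a 1 kelvin increment, so the same number is the slope
#'   per degree Celsius.
#' @param temps Numeric vector of at least two distinct temperatures, kelvin.
#' @param grid Conjugate-coordinate grid, nm.
#' @return A list of `pmf1d` objects, one per temperature.
#' @export
generate_multi_temperature <- function(u_curve, s_coeff, temps, grid) {
  temps <- as.numeric(temps)
  if (length(unique(temps)) < 2)
    stop("at least two distinct temperatures are required")
  if (length(grid) < 2) stop("'grid' must hold at least two points")
  if (is.function(u_curve)) {
    U <- u_curve(grid)
  } else {
    u_curve <- as.data.frame(u_curve)
    U <- stats::approx(u_curve[[1]], u_curve[[2]], xout = grid)$y
    if (any(is.na(U))) stop("'grid' extends beyond the tabulated U(G)")
  }
  lapply(temps, function(tt) {
    f_kj <- U - tt * (s_coeff * grid)
    pmf1d(grid = grid, values = kjmol_to_kbt(f_kj - min(f_kj), tt),
          counts = NULL, temperature = tt, coordinate_label = "conj")
  })
}

#' Synthetic bell-shaped rotation-extension curve
#'
#' Emulates the rotation-extension curve of a torsionally constrained
#' duplex in a magnetic tweezer: extension rises linearly with magnet turns
#' in the negative-plectoneme regime, passes through a smooth quadratic cap
#' of half-width `plateau_halfwidth` centred on the torsion-relaxed point,
#' and falls linearly in the positive-plectoneme regime.  The cap blends
#' the two slopes so that the extrapolated linear branches always cross at
#' `center_turn` exactly.  Gaussian noise of standard deviation `noise_sd`
#' is added and the true centre is recorded for recovery tests.
#'
#' @param center_turn True torsion-relaxed point, turns.
#' @param left_slope Rising slope, micrometre/turn (> 0).
#' @param right_slope Falling slope, micrometre/turn (< 0).
#' @param plateau_halfwidth Half-width of the smooth cap, turns (>= 0).
#' @param n_points Number of sampled rotations (>= 8).
#' @param noise_sd Gaussian noise on extension, micrometre.
#' @param seed Integer seed.
#' @param span Half-range of sampled turns about the centre (default 25).
#' @param peak_extension Extension at the torsion-relaxed point, micrometre.
#' @return A [rotation_extension_curve()] with attribute `true_center`.
#' @export
#' @examples
#' cur <- synth_rotation_extension(7, seed = 1)
#' fit_torsion_relaxed(cur)
synth_rotation_extension <- function(center_turn, left_slope = 0.05,
                                     right_slope = -0.05,
                                     plateau_halfwidth = 3, n_points = 51,
                                     noise_sd = 0.02, seed,
                                     span = 25, peak_extension = 2.5) {
  if (left_slope <= 0) stop("'left_slope' must be positive")
  if (right_slope >= 0) stop("'right_slope' must be negative")
  if (plateau_halfwidth < 0) stop("'plateau_halfwidth' must be >= 0")
  if (n_points < 8) stop("'n_points' must be at least 8 for two-line fitting")
  if (missing(seed)) stop("'seed' is mandatory")
  set.seed(as.integer(seed))
  turns <- seq(center_turn - span, center_turn + span, length.out = n_points)
  t_rel <- turns - center_turn
  a <- left_slope; b <- -right_slope; w <- plateau_halfwidth
  y <- numeric(n_points)
  if (w > 0) {
    # quadratic cap with slope a at -w and -b at +w; branches extrapolate
    # through the centre by construction
    cap <- abs(t_rel) <= w
    y[cap] <- peak_extension + a * t_rel[cap] -
      (a + b) * (t_rel[cap] + w)^2 / (4 * w)
    yl <- peak_extension - a * w   # cap value at -w
    yr <- peak_extension - b * w   # cap value at +w
    y[t_rel < -w] <- yl + a * (t_rel[t_rel < -w] + w)
    y[t_rel > w]  <- yr - b * (t_rel[t_rel > w] - w)
  } else {
    y <- peak_extension + ifelse(t_rel < 0, a * t_rel, -b * t_rel)
  }
  y <- y + stats::rnorm(n_points, 0, noise_sd)
  out <- rotation_extension_curve(turns, y,
                                  condition = list(synthetic = TRUE))
  attr(out, "true_center") <- center_turn
  out
}

#' Paired standalone/complex synthetic ensembles
#'
#' Generates a standalone ensemble from `base` and a second ensemble whose
#' mean (twist, conjugate coordinate) is displaced by `shift`, emulating the
#' deformation of a duplex upon protein binding relative to its standalone
#' simulation.
#'
#' @param base An [ensemble_spec()] for the standalone duplex.
#' @param shift Length-2 numeric `c(d_twist_deg, d_conj_nm)`.
#' @param seed Integer seed for the pair (the two members use derived seeds).
#' @return A list with elements `standalone` and `complex`.
#' @export
synth_complex_pair <- function(base, shift, seed) {
  if (!inherits(base, "ensemble_spec")) stop("'base' must be an ensemble_spec")
  if (length(shift) != 2 || any(!is.finite(shift)))
    stop("'shift' must be two finite numbers (deg, nm)")
  if (missing(seed)) stop("'seed' is mandatory")
  seed <- as.integer(seed)
  sa <- base; sa$seed <- seed
  standalone <- sample_pair_ensemble(sa)
  cc <- base$constants
  cc2 <- coupling_constants(cc$k_omega, cc$k_conj, cc$k_cross,
                            cc$omega0 + shift[1], cc$conj0 + shift[2],
                            coordinate_label = cc$coordinate_label)
  sb <- base; sb$constants <- cc2; sb$seed <- seed + 1L
  complex <- sample_pair_ensemble(sb)
  complex$conditions$complex <- TRUE
  list(standalone = standalone, complex = complex)
}
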