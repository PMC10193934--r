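#' Energy/entropy decomposition of multi-temperature free-energy profiles
#'
#' Given one-dimensional free-energy profiles F(G; T) at two or more
#' temperatures, solves per grid point the least-squares system
#' \deqn{F(G; T_i) = U(G) - T_i\, S(G)}
#' under the approximation that U and S are themselves
#' temperature-insensitive, and extracts the entropy slope
#' `k_SG = dS/dG` by a linear fit of S(G) over `fit_window`.
#'
#' Because each input profile is min-referenced at its own temperature, U
#' and S are recovered only up to G-independent offsets; the slope `k_SG`
#' is unaffected by any such offset.
#'
#' @param pmfs List of [pmf1d()] objects (values in kBT of their own
#'   temperature, `temperature` field set).  Profiles on different grids
#'   are interpolated onto the coarsest grid over the common range.
#' @param fit_window Length-2 numeric (nm) over which to fit the entropy
#'   slope; default the full common grid.
#' @return An object of class `entropy_decomposition`: `grid` (nm), `U`
#'   (kJ/mol), `S` (kJ/(mol K)), `k_SG` (kJ/(mol K nm), numerically equal
#'   to kJ/(mol degC nm)), `k_SG_stderr`, `fit_window`, and per-point rms
#'   `residuals` (kJ/mol).
#' @export
#' @examples
#' pmfs <- generate_multi_temperature(function(g) 400 * (g - 0.5)^2,
#'                                    s_coeff = 0.024,
#'                                    temps = c(285, 295, 305, 315),
#'                                    grid = seq(0.3, 0.7, by = 0.01))
#' decompose_U_S(pmfs)$k_SG
decompose_U_S <- function(pmfs, fit_window = NULL) {
  if (!is.list(pmfs) || length(pmfs) < 2)
    stop("need free-energy profiles at >= 2 temperatures")
  if (!all(vapply(pmfs, inherits, logical(1), "pmf1d")))
    stop("all elements of 'pmfs' must be pmf1d objects")
  temps <- vapply(pmfs, function(p) p$temperature, numeric(1))
  if (length(unique(temps)) < 2)
    stop("temperatures are degenerate: need >= 2 distinct values")
  grids <- lapply(pmfs, function(p) p$grid)
  same <- all(vapply(grids, function(g)
    length(g) == length(grids[[1]]) && all(g == grids[[1]]), logical(1)))
  if (same) {
    grid <- grids[[1]]
    Fk <- vapply(pmfs, function(p) p$values, numeric(length(grid)))
  } else {
    lo <- max(vapply(grids, min, numeric(1)))
    hi <- min(vapply(grids, max, numeric(1)))
    if (lo >= hi) stop("profiles have no overlapping grid range")
    coarse <- grids[[which.min(vapply(grids, length, integer(1)))]]
    grid <- coarse[coarse >= lo & coarse <= hi]
    if (length(grid) < 2) stop("overlapping grid is degenerate")
    Fk <- vapply(seq_along(pmfs), function(i)
      stats::approx(grids[[i]], pmfs[[i]]$values, xout = grid)$y,
      numeric(length(grid)))
  }
  # to kJ/mol of each profile's own temperature
  Fkj <- sweep(Fk, 2, kbt_energy(1)$kjmol * temps, `*`)
  A <- cbind(1, -temps)
  co <- qr.coef(qr(A), t(Fkj))       # 2 x n_grid: U then S
  U <- co[1, ]; S <- co[2, ]
  res <- sqrt(colMeans((A %*% co - t(Fkj))^2))
  if (is.null(fit_window)) fit_window <- range(grid)
  sel <- grid >= fit_window[1] & grid <= fit_window[2]
  if (sum(sel) < 2) stop("'fit_window' contains fewer than 2 grid points")
  sfit <- stats::lm(S[sel] ~ grid[sel])
  structure(list(grid = grid, U = U, S = S,
                 k_SG = unname(stats::coef(sfit)[2]),
                 k_SG_stderr = unname(
                   suppressWarnings(summary(sfit)$coefficients[2, 2])),
                 fit_window = fit_window, residuals = res,
                 temperatures = temps),
            class = "entropy_decomposition")
}

#' @export
print.entropy_decomposition <- function(x, ...) {
  cat("Energy/entropy decomposition over", length(x$grid), "grid points,",
      length(x$temperatures), "temperatures (",
      paste(x$temperatures, collapse = ", "), "K )\n")
  cat(sprintf("  k_SG = %.6g kJ/(mol K nm)  [fit window %.3g..%.3g nm]\n",
              x$k_SG, x$fit_window[1], x$fit_window[2]))
  cat(sprintf("  rms decomposition residual: %.3g kJ/mol\n",
              max(x$residuals)))
  invisible(x)
}

#' Entropic groove-widening force from a temperature change
#'
#' The temperature-induced generalized force on the conjugate coordinate,
#' \deqn{\Delta f_G^T \approx k_{SG}\,\Delta T,}
#' converted from kJ/(mol nm) to kBT/nm at the working temperature.
#'
#' @param delta_T Temperature change, degrees Celsius (== kelvin increment).
#' @param k_SG Entropy slope, kJ/(mol K nm).
#' @param temperature Working temperature, kelvin, for the unit conversion.
#' @return Force in kBT/nm; linear in `delta_T`.
#' @export
#' @examples
#' thermal_force(1, 0.024, 295)  # ~0.0098 kBT/nm per degC
thermal_force <- function(delta_T, k_SG, temperature = 295) {
  kjmol_to_kbt(k_SG, temperature) * delta_T
}
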