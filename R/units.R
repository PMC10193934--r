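#' Thermal energy at a temperature
#'
#' @param temperature Absolute temperature in kelvin.
#' @return A list with components `joules` (kB*T, J) and `kjmol` (R*T, kJ/mol).
#' @export
#' @examples
#' kbt_energy(295)  # 4.074e-21 J, 2.453 kJ/mol
kbt_energy <- function(temperature) {
  if (!is.numeric(temperature) || length(temperature) != 1 ||
      !is.finite(temperature) || temperature <= 0)
    stop("'temperature' must be a single positive number (kelvin)")
  list(joules = .const$kB * temperature,
       kjmol  = .const$R * temperature / 1000)
}

#' Convert between kJ/mol and kB*T units
#'
#' @param x Energy (or energy-valued coefficient) in kJ/mol.
#' @param temperature Absolute temperature in kelvin.
#' @return `x / (R*T)`, i.e. the same quantity in kB*T units.
#' @export
#' @examples
#' kjmol_to_kbt(2.4526, 295)  # ~1
kjmol_to_kbt <- function(x, temperature) {
  rt <- kbt_energy(temperature)$kjmol
  x / rt
}

#' @rdname kjmol_to_kbt
#' @param x_kbt Quantity in kB*T units.
#' @export
kbt_to_kjmol <- function(x_kbt, temperature) {
  x_kbt * kbt_energy(temperature)$kjmol
}

#' Torsional rigidity in pN nm^2 from a per-bp twist stiffness
#'
#' Generic dimensional conversion
#' \deqn{C = k_\omega \,(180/\pi)^2\, h \, k_B T,}
#' taking a per-base-pair twist stiffness in kBT/deg^2 and a helical rise in
#' nm/bp to the torsional rigidity of the continuous rod, in pN nm^2.
#'
#' @param k_omega Per-bp twist stiffness, kBT/deg^2.
#' @param rise Helical rise, nm per bp.
#' @param temperature Absolute temperature, kelvin.
#' @return Torsional rigidity in pN nm^2.
#' @export
#' @examples
#' twist_rigidity_pnnm(0.18, 0.28, 295)  # ~674
twist_rigidity_pnnm <- function(k_omega, rise, temperature) {
  if (!is.numeric(k_omega) || k_omega < 0) stop("'k_omega' must be >= 0")
  if (!is.numeric(rise) || rise <= 0) stop("'rise' must be positive")
  kbt_pnnm <- kbt_energy(temperature)$joules * 1e21  # 1 pN nm = 1e-21 J
  k_omega * (180 / pi)^2 * rise * kbt_pnnm
}
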