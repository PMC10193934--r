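# Physical constants (SI, CODATA 2018)
.const <- list(
  kB   = 1.380649e-23,     # Boltzmann constant, J/K
  R    = 8.314462618,      # gas constant, J/(mol K)
  e    = 1.602176634e-19,  # elementary charge, C
  eps0 = 8.8541878128e-12  # vacuum permittivity, F/m
)

#' Physical context for an analysis
#'
#' Bundles the absolute temperature, the solvent dielectric constant and the
#' reference monovalent-salt concentration used throughout a calculation.
#' All energies inside the package are expressed in units of `kB*T` at this
#' temperature; conversions to kJ/mol or pN nm happen only at the
#' input/output boundary.
#'
#' @param temperature Absolute temperature in kelvin (default 295 K).
#' @param dielectric_constant Relative dielectric constant of the solvent
#'   (default 78.4, water).
#' @param reference_salt Reference monovalent salt concentration in molar,
#'   at which salt-induced twist changes are defined to be zero (default 1 M).
#' @return An object of class `physical_context`.
#' @export
#' @examples
#' physical_context()
physical_context <- function(temperature = 295, dielectric_constant = 78.4,
                             reference_salt = 1) {
  if (!is.numeric(temperature) || length(temperature) != 1 || temperature <= 0)
    stop("'temperature' must be a single positive number (kelvin)")
  if (!is.numeric(dielectric_constant) || dielectric_constant <= 0)
    stop("'dielectric_constant' must be positive")
  if (!is.numeric(reference_salt) || reference_salt <= 0)
    stop("'reference_salt' must be positive (molar)")
  structure(list(temperature = temperature,
                 dielectric_constant = dielectric_constant,
                 reference_salt = reference_salt),
            class = "physical_context")
}

#' @export
print.physical_context <- function(x, ...) {
  cat("Physical context: T =", x$temperature, "K, eps_r =",
      x$dielectric_constant, ", reference salt =", x$reference_salt, "M\n")
  invisible(x)
}

#' Per-base-pair harmonic coupling constants
#'
#' The harmonic coupled deformation energy of one base-pair step is
#' \deqn{P^{bp} = \tfrac12 k_\omega (\Delta\omega)^2 +
#'               \tfrac12 k_X (\Delta X)^2 + k_{\omega X}\,\Delta\omega\,\Delta X,}
#' in units of `kB*T`, where \eqn{\Delta\omega} is the twist deviation
#' (degrees) from `omega0` and \eqn{\Delta X} the deviation (nm) of the
#' conjugate coordinate -- major groove width for RNA, diameter for DNA --
#' from `conj0`.  The stiffness matrix must be positive definite.
#'
#' @param k_omega Twist stiffness, kBT/deg^2 per bp (> 0).
#' @param k_conj Conjugate-coordinate modulus, kBT/nm^2 per bp (> 0).
#' @param k_cross Cross-coupling constant, kBT/(deg nm) per bp.
#' @param omega0 Equilibrium twist, degrees per bp step.
#' @param conj0 Equilibrium conjugate coordinate, nm.
#' @param coordinate_label Either `"groove_width"` or `"diameter"`.
#' @return An object of class `coupling_constants`.
#' @seealso [coupling_preset()] for the shipped RNA and DNA parameter sets.
#' @export
#' @examples
#' coupling_constants(0.18, 3.61, 0.43, 32.15, 0.52)
coupling_constants <- function(k_omega, k_conj, k_cross = 0,
                               omega0 = 0, conj0 = 0,
                               coordinate_label = c("groove_width", "diameter")) {
  coordinate_label <- match.arg(coordinate_label)
  for (nm in c("k_omega", "k_conj", "k_cross", "omega0", "conj0")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v))
      stop("'", nm, "' must be a single finite number")
  }
  if (k_omega <= 0 || k_conj <= 0)
    stop("'k_omega' and 'k_conj' must be positive")
  if (k_omega * k_conj - k_cross^2 <= 0)
    stop("stiffness matrix is not positive definite: k_omega*k_conj - k_cross^2 = ",
         signif(k_omega * k_conj - k_cross^2, 4), " <= 0")
  structure(list(k_omega = k_omega, k_conj = k_conj, k_cross = k_cross,
                 omega0 = omega0, conj0 = conj0,
                 coordinate_label = coordinate_label),
            class = "coupling_constants")
}

# 2x2 stiffness (precision) matrix in kBT units, twist first
stiffness_matrix <- function(constants) {
  matrix(c(constants$k_omega, constants$k_cross,
           constants$k_cross, constants$k_conj), 2, 2)
}

#' @export
print.coupling_constants <- function(x, digits = 4, ...) {
  cat("Per-bp harmonic coupling constants (", x$coordinate_label, "):\n", sep = "")
  cat(sprintf("  k_omega = %s kBT/deg^2\n  k_%s = %s kBT/nm^2\n  k_cross = %s kBT/(deg nm)\n",
              signif(x$k_omega, digits),
              if (x$coordinate_label == "diameter") "D" else "G",
              signif(x$k_conj, digits), signif(x$k_cross, digits)))
  cat(sprintf("  reference point: omega0 = %s deg, conj0 = %s nm\n",
              signif(x$omega0, digits), signif(x$conj0, digits)))
  invisible(x)
}

#' Load a configuration file of constants and defaults
#'
#' Reads the YAML (or JSON) configuration holding the physical context,
#' electrostatic parameters, entropy coefficient, geometry parameters, PMF
#' binning defaults and the coupling-constant presets.  With no argument the
#' configuration shipped with the package is returned.
#'
#' @param path Path to a YAML or JSON configuration file, or `NULL` for the
#'   package default.
#' @return A nested list mirroring the file.
#' @export
load_config <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "default-config.yaml", package = "twistcouple")
  if (!file.exists(path)) stop("config file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else
    yaml::read_yaml(path)
}

#' Coupling-constant presets
#'
#' Returns one of the parameter sets shipped in the default configuration:
#' `"rna-eq3"`, the fitted A-RNA twist--groove-width constants
#' (k_omega = 0.18 kBT/deg^2, k_G = 3.61 kBT/nm^2, k_cross = 0.43
#' kBT/(deg nm), reference point 32.15 deg / 0.52 nm, averaging length
#' 19 bp), and `"dna-prev"`, the B-DNA twist--diameter constants
#' (0.18, 263, 4.5).
#'
#' @param name Preset name.
#' @param config Optional configuration list from [load_config()].
#' @return A `coupling_constants` object with an `n_bp` attribute giving the
#'   preset's default chain-averaging length.
#' @export
#' @examples
#' coupling_preset("rna-eq3")
coupling_preset <- function(name = c("rna-eq3", "dna-prev"), config = NULL) {
  name <- match.arg(name)
  if (is.null(config)) config <- load_config()
  p <- config$presets[[name]]
  if (is.null(p)) stop("preset '", name, "' not found in config")
  cc <- coupling_constants(p$k_omega, p$k_conj, p$k_cross, p$omega0, p$conj0,
                           coordinate_label = p$coordinate_label)
  attr(cc, "n_bp") <- if (is.null(p$n_bp)) 1L else as.integer(p$n_bp)
  cc
}
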