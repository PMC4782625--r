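#' Physical constants used throughout the package
#'
#' Returns the CODATA 2018 values of the physical constants the model depends
#' on, in SI units. These are the constants entering the Debye-Hueckel
#' parameter, the screened pair energies, the Stokes-Einstein diffusion
#' constant and the Smoluchowski basal rate.
#'
#' @return A named list: `faraday` (C mol^-1), `gas` (J mol^-1 K^-1),
#'   `boltzmann` (J K^-1), `avogadro` (mol^-1), `vacuum_permittivity`
#'   (F m^-1), `elementary_charge` (C), and `joules_per_kcal`.
#' @export
#' @examples
#' physical_constants()$boltzmann
physical_constants <- function() {
  list(
    faraday             = 96485.33212,
    gas                 = 8.314462618,
    boltzmann           = 1.380649e-23,
    avogadro            = 6.02214076e23,
    vacuum_permittivity = 8.8541878128e-12,
    elementary_charge   = 1.602176634e-19,
    joules_per_kcal     = 4184
  )
}

#' Solution conditions
#'
#' Bundles the solution parameters of the electrostatic model. The defaults
#' are physiological saline at room temperature: ionic strength 150 mM,
#' temperature 298.15 K, viscosity 0.90e-3 kg s^-1 m^-1 and relative
#' dielectric constant 80.
#'
#' @param ionic_strength_mM Ionic strength in mM (mmol/L). Stored internally
#'   in mol m^-3, numerically equal to the mM value.
#' @param temperature Absolute temperature in K.
#' @param viscosity Solvent viscosity in kg s^-1 m^-1.
#' @param dielectric Relative dielectric constant (dimensionless).
#' @return An object of class `solution_conditions`.
#' @export
#' @examples
#' cond <- solution_conditions()
#' debye_parameter(cond)  # ~0.126 1/Angstrom
solution_conditions <- function(ionic_strength_mM = 150,
                                temperature = 298.15,
                                viscosity = 0.90e-3,
                                dielectric = 80) {
  vals <- c(ionic_strength_mM = ionic_strength_mM, temperature = temperature,
            viscosity = viscosity, dielectric = dielectric)
  if (any(!is.finite(vals)))
    stop("solution_conditions: all fields must be finite", call. = FALSE)
  if (ionic_strength_mM < 0)
    stop("solution_conditions: ionic strength must be non-negative", call. = FALSE)
  if (temperature <= 0 || viscosity <= 0 || dielectric <= 0)
    stop("solution_conditions: temperature, viscosity and dielectric constant must be strictly positive",
         call. = FALSE)
  structure(
    list(
      ionic_strength = ionic_strength_mM,  # mol m^-3 == mM
      temperature    = temperature,
      viscosity      = viscosity,
      dielectric     = dielectric,
      constants      = physical_constants()
    ),
    class = "solution_conditions"
  )
}

#' @export
print.solution_conditions <- function(x, ...) {
  cat("Solution conditions\n")
  cat(sprintf("  ionic strength : %g mM\n", x$ionic_strength))
  cat(sprintf("  temperature    : %g K\n", x$temperature))
  cat(sprintf("  viscosity      : %g kg/s/m\n", x$viscosity))
  cat(sprintf("  dielectric     : %g\n", x$dielectric))
  cat(sprintf("  Debye parameter: %.5f 1/Angstrom\n", debye_parameter(x)))
  invisible(x)
}

# thermal energy per mole in kcal/mol
.rt_kcal <- function(cond) {
  cond$constants$gas * cond$temperature / cond$constants$joules_per_kcal
}

#' Debye-Hueckel screening parameter
#'
#' kappa = sqrt(2 F^2 I / (eps_o eps_r R T)), the inverse Debye screening
#' length of the electrolyte, returned in 1/Angstrom.
#'
#' @param cond A [solution_conditions()] object.
#' @return kappa in Angstrom^-1 (non-negative scalar).
#' @export
debye_parameter <- function(cond) {
  stopifnot(inherits(cond, "solution_conditions"))
  k <- cond$constants
  kappa_m <- sqrt(2 * k$faraday^2 * cond$ionic_strength /
                    (k$vacuum_permittivity * cond$dielectric * k$gas * cond$temperature))
  kappa_m * 1e-10
}
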