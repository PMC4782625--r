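#' Rod geometry for fondaparinux
#'
#' Fondaparinux is modelled as a prolate rod (ellipsoid) with major semiaxis
#' `l` and minor semiaxis `w`, plus a hydrodynamic radius for its diffusion
#' constant. The default dimensions (l = 15 A, w = 5 A, r' = 7 A) are model
#' defaults for a pentasaccharide-scale rod.
#'
#' @param major_semiaxis Major semiaxis l in Angstrom.
#' @param minor_semiaxis Minor semiaxis w in Angstrom.
#' @param hydrodynamic_radius Hydrodynamic radius in Angstrom.
#' @return An object of class `rod_geometry`.
#' @export
rod_geometry <- function(major_semiaxis = 15, minor_semiaxis = 5,
                         hydrodynamic_radius = 7) {
  if (!(minor_semiaxis > 0) || major_semiaxis < minor_semiaxis)
    stop("rod_geometry: require l >= w > 0", call. = FALSE)
  if (2 * major_semiaxis / minor_semiaxis <= 1)
    stop("rod_geometry: require 2l/w > 1 so log(2l/w) is positive", call. = FALSE)
  if (hydrodynamic_radius <= 0)
    stop("rod_geometry: hydrodynamic radius must be positive", call. = FALSE)
  structure(list(l = major_semiaxis, w = minor_semiaxis,
                 hydrodynamic_radius = hydrodynamic_radius),
            class = "rod_geometry")
}

#' Sphere geometry for the polymer scaffold
#'
#' @param radius_nm Hydrodynamic radius r_H in nm (as quoted for polymer
#'   cores); stored internally in Angstrom.
#' @return An object of class `sphere_geometry` with element `r_H` (Angstrom).
#' @export
sphere_geometry <- function(radius_nm = 4) {
  if (!is.finite(radius_nm) || radius_nm <= 0)
    stop("sphere_geometry: radius must be positive", call. = FALSE)
  structure(list(r_H = radius_nm * 10, radius_nm = radius_nm),
            class = "sphere_geometry")
}

#' Stokes-Einstein diffusion constant
#'
#' D = k_B T / (6 pi eta r'), for a hydrodynamic radius r' in Angstrom.
#'
#' @param r_hydro Hydrodynamic radius in Angstrom.
#' @param cond A [solution_conditions()].
#' @return D in m^2 s^-1.
#' @export
diffusion_constant <- function(r_hydro, cond) {
  stopifnot(inherits(cond, "solution_conditions"))
  if (!is.finite(r_hydro) || r_hydro <= 0)
    stop("diffusion_constant: radius must be positive", call. = FALSE)
  k <- cond$constants
  k$boltzmann * cond$temperature / (6 * pi * cond$viscosity * r_hydro * 1e-10)
}

#' Sphere-rod interaction radius
#'
#' R_x = l / ln(2l/w) for a rod with major and minor semiaxes l and w.
#'
#' @param rod A [rod_geometry()].
#' @return R_x in Angstrom.
#' @export
interaction_radius <- function(rod) {
  stopifnot(inherits(rod, "rod_geometry"))
  rod$l / log(2 * rod$l / rod$w)
}

#' Smoluchowski diffusion-limited basal association rate
#'
#' k_a0 = 4 pi N_A (D_A + D_B) R_x, the diffusion-controlled association rate
#' of two uniformly reactive molecules, converted to M^-1 s^-1 (R_x is given
#' in Angstrom; Avogadro's number carries the per-mole conversion and the
#' m^3 -> L factor is applied).
#'
#' @param D_A,D_B Diffusion constants in m^2 s^-1.
#' @param R_x Interaction radius in Angstrom.
#' @return k_a0 in M^-1 s^-1.
#' @export
basal_rate <- function(D_A, D_B, R_x) {
  if (any(c(D_A, D_B, R_x) <= 0))
    stop("basal_rate: all inputs must be positive", call. = FALSE)
  NA_const <- physical_constants()$avogadro
  4 * pi * NA_const * (D_A + D_B) * (R_x * 1e-10) * 1000
}

#' Electrostatically modulated association rate (Schreiber relation)
#'
#' ln k_a = ln k_a0 - Delta U / (k_B T (1 + kappa a)): favourable (negative)
#' interaction energies accelerate association above the diffusion limit;
#' at Delta U = 0, or in the full-screening limit kappa -> Inf, k_a = k_a0.
#' Delta U is supplied per mole (kcal mol^-1) and divided by RT, which is the
#' per-mole equivalent of k_B T per molecule.
#'
#' @param ka0 Basal rate in M^-1 s^-1.
#' @param dU Interaction energy Delta U in kcal mol^-1.
#' @param cond A [solution_conditions()].
#' @param a Minimal approach distance in Angstrom.
#' @return k_a in M^-1 s^-1.
#' @export
association_rate <- function(ka0, dU, cond, a = 8.5) {
  stopifnot(inherits(cond, "solution_conditions"))
  if (ka0 <= 0) stop("association_rate: ka0 must be positive", call. = FALSE)
  if (a <= 0) stop("association_rate: a must be positive", call. = FALSE)
  kappa <- debye_parameter(cond)
  ka0 * exp(-dU / (.rt_kcal(cond) * (1 + kappa * a)))
}

#' Cubic simulation-cell edge from composition and density
#'
#' Edge length of a cubic cell holding `n_waters` water molecules plus
#' solutes of total molar mass `solute_mass` at the given mass density.
#' The default solute mass corresponds to one fondaparinux decaanion
#' (~1498.2 g/mol), one trication binding group (~149.3 g/mol) and seven
#' sodium counterions.
#'
#' @param n_waters Number of water molecules.
#' @param solute_mass Total solute molar mass in g mol^-1.
#' @param density Mass density in g cm^-3.
#' @return Edge length in Angstrom.
#' @export
#' @examples
#' round(md_box_edge(2600))  # 43
md_box_edge <- function(n_waters = 2600, solute_mass = 1808.4, density = 1.0) {
  if (n_waters < 0 || solute_mass < 0 || density <= 0)
    stop("md_box_edge: invalid composition", call. = FALSE)
  mass <- n_waters * 18.01528 + solute_mass               # g/mol
  vol_cm3 <- mass / (physical_constants()$avogadro * density)
  (vol_cm3 * 1e24)^(1 / 3)                                 # 1 cm^3 = 1e24 A^3
}
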