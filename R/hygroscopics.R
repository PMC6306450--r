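# Deliquescence physics: shifted humidity, water-uptake fits, POD
# concentration and the deliquescent droplet volume.

#' Shifted relative humidity and deliquescence state
#'
#' Adjuvants shift the point of deliquescence (POD) of an ionic solution
#' by an amount `xi`; the water-uptake functions are then evaluated at the
#' shifted humidity `Phi`.  If `H + xi` exceeds the solute POD the
#' solution is deliquescent (`above_POD`) and `Phi = min(H + xi, 0.97)`;
#' otherwise hygroscopic water absorption is disabled and the droplet
#' evaporates without deliquescent growth.
#'
#' @param H ambient relative humidity, fraction in `[0, 1]`.
#' @param xi POD shift from the adjuvant, RH fraction.
#' @param POD_AI point of deliquescence of the pure solute, RH fraction.
#' @return A list with `Phi` (shifted humidity, `NA` when below the POD)
#'   and `above_POD` (logical).
#' @export
#' @examples
#' shifted_humidity(0.70, 0.05, 0.32)   # Phi = 0.75, deliquescent
#' shifted_humidity(0.25, 0,    0.32)   # below the POD
shifted_humidity <- function(H, xi, POD_AI) {
  stopifnot(H >= 0, H <= 1, xi >= 0, xi <= 1, POD_AI >= 0, POD_AI <= 1)
  if (H + xi > POD_AI) {
    list(Phi = min(H + xi, 0.97), above_POD = TRUE)
  } else {
    list(Phi = NA_real_, above_POD = FALSE)
  }
}

#' Final solution weight percentage of the solute
#'
#' The maximum weight percentage a deliquescent solution can reach before
#' crystallisation, as a function of the shifted relative humidity.
#' Strictly decreasing: drier air permits a more concentrated solution.
#'
#' @param Phi shifted relative humidity, fraction in `[0, 0.97]`.
#' @param material a [hygro_material()]; default CaCl2.
#' @return weight percent, in (0, 100).
#' @export
#' @examples
#' mass_percent(0.75)   # about 22.5 % for CaCl2
mass_percent <- function(Phi, material = hygro_material()) {
  if (any(Phi < 0 | Phi > 0.97))
    stop("mass_percent: Phi must lie in [0, 0.97]")
  material$c_mass_pct(Phi)
}

#' Equilibrium water absorption per unit mass of solute
#'
#' Mass of water a deliquescent solute holds at equilibrium per unit
#' solute mass (g water / g solute), strictly increasing in humidity.
#' CaCl2 absorbs roughly 14 times its own mass at 95 % RH.
#'
#' @inheritParams mass_percent
#' @return g water per g solute, positive.
#' @export
#' @examples
#' m_inf(0.95)   # about 14 for CaCl2
m_inf <- function(Phi, material = hygro_material()) {
  if (any(Phi < 0 | Phi > 0.97))
    stop("m_inf: Phi must lie in [0, 0.97]")
  material$m_inf(Phi)
}

#' Maximum solution concentration before crystallisation
#'
#' Converts the weight-percent ceiling into a molar concentration:
#' `c_POD = c_mass_pct(Phi) * rho_AI / (100 * M_w_AI)`.  Only defined when
#' the solution is deliquescent (above the POD); the below-POD branch of
#' the evaporation model does not use it.
#'
#' @param Phi shifted relative humidity, fraction in `[0, 0.97]`.
#' @param p a [cuticle_params()] object (supplies `rho_AI`, `M_w_AI` and
#'   the material).
#' @return concentration, mol/m^3.
#' @export
#' @examples
#' pod_concentration(0.75, cuticle_params())   # about 4380 mol/m^3
pod_concentration <- function(Phi, p) {
  mass_percent(Phi, p$material) * p$rho_AI / (100 * p$M_w_AI)
}

#' Deliquescent droplet volume
#'
#' The minimum water volume a droplet with solute content
#' `c_AI_surf * V` can hold at the given shifted humidity:
#' `V_Del = m_inf(Phi) * M_w_AI * c_AI_surf * V / rho_H2O`.  Evaporation
#' stalls as the droplet volume approaches `V_Del` and reverses below it
#' (hygroscopic absorption).  Since `c_AI_surf * V` is the moles of
#' solute in the drop, `V_Del` is proportional to solute content and
#' vanishes with it.
#'
#' @param c_AI_surf solute concentration in the drop, mol/m^3.
#' @param V droplet water volume, m^3.
#' @param Phi shifted relative humidity, fraction.
#' @param p a [cuticle_params()] object.
#' @return volume, m^3.
#' @export
deliquescent_volume <- function(c_AI_surf, V, Phi, p) {
  stopifnot(all(c_AI_surf >= 0), all(V >= 0))
  m_inf(Phi, p$material) * p$M_w_AI * c_AI_surf * V / p$rho_H2O
}
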