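# Droplet-side rate laws: pinned (constant contact radius) evaporation,
# de-pinned (constant contact angle) evaporation with and without
# hygroscopic deliquescent growth, and the surface solute balance with
# irreversible ion binding.

#' Evaporation rates in constant-contact-radius mode
#'
#' While the contact line is pinned the contact angle relaxes and the
#' volume shrinks at the quasi-steady diffusion-limited rates
#' `dtheta/dt = -Lambda (1 + cos theta)^2 f(theta) / r_drop_0^2` and
#' `dV/dt = -pi Lambda r_drop_0 f(theta)`.
#'
#' @param theta current contact angle, radians.
#' @param r_drop_0 pinned contact radius, m.
#' @param Lambda evaporation constant, m^2/s.
#' @param f_fun evaluator for the Popov function (defaults to the direct
#'   quadrature; the simulator passes the cached interpolant).
#' @return list with `dtheta_dt` (rad/s) and `dV_dt` (m^3/s), both <= 0.
#' @export
ccr_rates <- function(theta, r_drop_0, Lambda, f_fun = popov_f) {
  f <- f_fun(theta)
  list(dtheta_dt = -Lambda * (1 + cos(theta))^2 * f / r_drop_0^2,
       dV_dt = -pi * Lambda * r_drop_0 * f)
}

#' Evaporation rate in constant-contact-angle mode with deliquescence
#'
#' Above the point of deliquescence the diffusion-limited rate
#' `-pi Lambda f(theta_rec) (3 g(theta_rec) V / pi)^(1/3)` is modulated by
#' a logistic decay factor `chi_bar / V_0 * V * (V / V_Del - 1)` that
#' drives the volume towards (never through) the deliquescent volume
#' `V_Del`, and by the crystallisation cap `(1 - c_AI_surf / c_POD)` that
#' switches evaporation off as the solution saturates.  A diffusive
#' water-exchange term with the cuticle surface closes the water balance
#' (supplied by the caller as `water_flux_term`, m^3/s, positive into the
#' drop).
#'
#' @param V droplet water volume, m^3.
#' @param c_AI_surf droplet solute concentration, mol/m^3.
#' @param V_Del deliquescent volume, m^3 (guarded below by `V_Del_floor`).
#' @param c_POD crystallisation concentration, mol/m^3.
#' @param theta_rec receding contact angle, radians.
#' @param Lambda evaporation constant, m^2/s.
#' @param chi_bar concentration-scaled logistic constant (dimensionless).
#' @param V_0 initial droplet volume, m^3.
#' @param water_flux_term diffusive water volume exchange, m^3/s.
#' @param f_rec value of the Popov function at `theta_rec`.
#' @param V_Del_floor smooth lower guard on `V_Del` (default 1e-18 m^3),
#'   keeping the logistic factor finite as the solute is depleted.
#' @return `dV/dt`, m^3/s: negative while `V > V_Del`, zero at the
#'   deliquescent equilibrium, positive (absorption) below it.
#' @export
cca_hygroscopic_rate <- function(V, c_AI_surf, V_Del, c_POD, theta_rec,
                                 Lambda, chi_bar, V_0, water_flux_term = 0,
                                 f_rec = popov_f(theta_rec),
                                 V_Del_floor = 1e-18) {
  V <- pmax(V, 0)
  V_Del <- pmax(V_Del, V_Del_floor)
  popov <- -pi * Lambda * f_rec * (3 * cap_g(theta_rec) * V / pi)^(1 / 3)
  logistic <- chi_bar / V_0 * V * (V / V_Del - 1)
  cap <- 1 - c_AI_surf / c_POD
  popov * logistic * cap + water_flux_term
}

#' Evaporation rate in constant-contact-angle mode below the POD
#'
#' Below the point of deliquescence there is no hygroscopic growth: the
#' droplet evaporates at the bare diffusion-limited rate
#' `-pi Lambda f(theta_rec) (3 g(theta_rec) V / pi)^(1/3)` plus the same
#' diffusive water-exchange term as the deliquescent branch.
#'
#' @inheritParams cca_hygroscopic_rate
#' @return `dV/dt`, m^3/s.
#' @export
cca_below_pod_rate <- function(V, theta_rec, Lambda, water_flux_term = 0,
                               f_rec = popov_f(theta_rec)) {
  V <- pmax(V, 0)
  -pi * Lambda * f_rec * (3 * cap_g(theta_rec) * V / pi)^(1 / 3) +
    water_flux_term
}

#' Droplet solute balance with ion binding
#'
#' Rate of change of the moles of solute in the droplet,
#' `d(V c_AI_surf)/dt = -k c_AI_surf + S * [D_AI d(eps c_AI)/dx]|x=0`,
#' where `S = eta_pore * A_drop * A_Pi` scales the one-dimensional pore
#' flux to the droplet footprint.  The binding term `-k c_AI_surf`
#' irreversibly traps ions at the cuticle surface and accumulates into
#' `m_bound`.
#'
#' @param c_AI_surf droplet solute concentration, mol/m^3.
#' @param k ion-binding rate constant, m^3/s.
#' @param S pore-weighted footprint area `eta_pore * A_drop * A_Pi`, m^2.
#' @param grad_eps_cAI_surface surface gradient `d(eps c_AI)/dx|x=0`,
#'   mol/m^4 (negative when the concentration falls into the cuticle).
#' @param D_AI_surface effective diffusivity at the surface, m^2/s.
#' @return list with `dn_dt` (mol/s, change of drop solute moles) and
#'   `dm_bound_dt` (mol/s, accumulation of bound solute).
#' @export
surface_ai_balance <- function(c_AI_surf, k, S, grad_eps_cAI_surface,
                               D_AI_surface) {
  list(dn_dt = -k * c_AI_surf + S * D_AI_surface * grad_eps_cAI_surface,
       dm_bound_dt = k * c_AI_surf)
}
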