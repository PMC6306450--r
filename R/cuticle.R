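# Cuticle interior: swelling aqueous pores, Langmuir water adsorption,
# fractal-tortuosity effective diffusivities and the finite-volume
# discretization of the coupled solute/water diffusion equations.

#' Pore radius from adsorbed water density
#'
#' Geometric relation between the monolayer of water adsorbed on the pore
#' wall and the open pore radius:
#' `r_p = r_H2O * (1 + 1 / sin(1 / (Gamma * r_H2O^2 * N_A)))`.
#' Strictly increasing in `Gamma`; at the Langmuir saturation density the
#' pore reaches its maximum radius.
#'
#' @param Gamma adsorbed water, mol/m^2, in `(0, Gamma_S]`.
#' @param p a [cuticle_params()] object.
#' @return pore radius, m.
#' @export
pore_radius_from_gamma <- function(Gamma, p) {
  if (any(Gamma <= 0)) stop("pore_radius_from_gamma: Gamma must be > 0")
  s <- 1 / (Gamma * p$r_H2O^2 * p$N_A)
  if (any(s >= pi / 2))
    stop("pore_radius_from_gamma: Gamma below the geometric minimum")
  p$r_H2O * (1 + 1 / sin(s))
}

#' Adsorbed water density from pore radius
#'
#' Inverse of [pore_radius_from_gamma()]:
#' `Gamma = 1 / (r_H2O^2 * N_A * asin(1 / (r_p / r_H2O - 1)))`.
#' Defined for `r_p > 2 * r_H2O` (arcsine argument below one).
#'
#' @param r_p pore radius, m.
#' @param p a [cuticle_params()] object.
#' @return adsorbed water, mol/m^2.
#' @export
#' @examples
#' p <- cuticle_params()
#' gamma_from_pore_radius(p$r_p_max, p)   # Langmuir saturation, 9.6832e-4
gamma_from_pore_radius <- function(r_p, p) {
  arg <- 1 / (r_p / p$r_H2O - 1)
  if (any(arg >= 1))
    stop("gamma_from_pore_radius: r_p must exceed 2 * r_H2O")
  1 / (p$r_H2O^2 * p$N_A * asin(arg))
}

#' Areal porosity of the cuticle cross-section
#'
#' Fraction of the cuticle cross-section occupied by aqueous pores,
#' with pores evenly distributed at density `eta_pore` and circular cross
#' sections: `eps = (n_0 + 1) * pi * r_p^2 / L^2` with
#' `n_0 = eta_pore * L^2`.
#'
#' @param r_p pore radius, m (vectorised).
#' @param p a [cuticle_params()] object.
#' @return porosity in (0, 1); errors if the configuration implies
#'   `eps >= 1`.
#' @export
porosity <- function(r_p, p) {
  eps <- (p$eta_pore * p$L^2 + 1) * pi * r_p^2 / p$L^2
  if (any(eps >= 1))
    stop("porosity: pore density times pore area exceeds the surface")
  eps
}

#' Effective diffusivity in tortuous pores
#'
#' Fractal-tortuosity scaling `D = D_bulk * eps^(F_s / (2 - F_s))`.  At
#' `F_s -> 1` the exponent degenerates to the classical porosity scaling
#' `D = D_bulk * eps`; larger `F_s` (more tortuous pores) suppresses
#' transport.
#'
#' @param eps porosity in (0, 1).
#' @param D_bulk bulk (free-solution) diffusivity, m^2/s.
#' @param F_s fractal scaling dimension, `1 < F_s < 2`.
#' @return effective diffusivity, m^2/s.
#' @export
effective_diffusivity <- function(eps, D_bulk, F_s) {
  stopifnot(all(eps > 0), all(eps < 1), F_s > 1, F_s < 2, D_bulk > 0)
  D_bulk * eps^(F_s / (2 - F_s))
}

#' Langmuir isotherm for adsorbed pore water
#'
#' Monolayer adsorption of water to the aqueous pore wall:
#' `Gamma = Gamma_S * beta * c / (1 + beta * c)`, saturating at `Gamma_S`.
#'
#' @param c_H2O local water concentration, mol/m^3 (vectorised).
#' @param beta Langmuir equilibrium parameter, m^3/mol.
#' @param Gamma_S saturation density, mol/m^2.
#' @return adsorbed density, mol/m^2, in `[0, Gamma_S)`.
#' @export
langmuir_gamma <- function(c_H2O, beta, Gamma_S) {
  stopifnot(all(c_H2O >= 0))
  Gamma_S * beta * c_H2O / (1 + beta * c_H2O)
}

# Local pore state as a function of water concentration.  Returns the
# adsorbed density, pore radius, porosity, effective diffusivities and
# the derivatives needed for the chain-rule capacity of the water
# equation:
#   d(eps*cW)/dt + (2/r_p)(1-eps) dGamma/dt = div(D grad(eps*cW))
# => C(cW) dcW/dt = div(...),
#    C = eps + cW*deps/dcW + (2/r_p)(1-eps)*dGamma/dcW.
pore_state <- function(cW, p, d) {
  beta <- d$beta_H2O; GS <- d$Gamma_S
  cW <- pmax(cW, 1e-6 * d$c_H2O_pure)          # guard: physics needs cW > 0
  Gam <- GS * beta * cW / (1 + beta * cW)
  dGam <- GS * beta / (1 + beta * cW)^2
  s <- 1 / (Gam * p$r_H2O^2 * p$N_A)
  rp <- p$r_H2O * (1 + 1 / sin(s))
  # dr_p/dGamma = r_H2O * cos(s) * s / (sin(s)^2 * Gamma)
  drp <- p$r_H2O * cos(s) * s / (sin(s)^2 * Gam)
  eps <- (p$eta_pore * p$L^2 + 1) * pi * rp^2 / p$L^2
  deps <- 2 * eps / rp * drp * dGam            # deps/dcW
  expo <- p$F_s / (2 - p$F_s)
  DA <- p$D_AI_bulk * eps^expo
  DW <- p$D_H2O_bulk * eps^expo
  capacity <- eps + cW * deps + (2 / rp) * (1 - eps) * dGam
  list(Gamma = Gam, r_p = rp, eps = eps, D_AI = DA, D_H2O = DW,
       capacity = capacity)
}

#' Initial cuticle field
#'
#' Builds the node-centred finite-volume grid over `[0, b]` and the
#' initial state: no solute in the interior, interior water at the
#' pure-water concentration, pores at `gamma * r_p_max` with the matching
#' adsorbed density, and surface boundary values set by the droplet
#' (solute at the applied concentration; water reduced by the partial
#' molar volume of the dissolved solute).
#'
#' @param p a [cuticle_params()] object.
#' @param d derived constants from [derive_constants()]; computed if
#'   missing.
#' @return A list of class `cuticle_field` with node positions `x`,
#'   spacing `dx`, vectors `c_AI`, `c_H2O`, `Gamma`, `r_p`, `eps`,
#'   `D_AI`, `D_H2O`, and boundary values `c_AI_surface`, `c_H2O_surface`,
#'   `c_H2O_bath`.
#' @export
initialize_field <- function(p, d = NULL) {
  if (is.null(d)) d <- derive_constants(p, t_rec = FALSE)
  Nx <- as.integer(p$N_x)
  dx <- p$b / Nx
  x <- (seq_len(Nx) - 0.5) * dx
  cW <- rep(d$c_H2O_pure, Nx)
  st <- pore_state(cW, p, d)
  c_surf <- p$c_AI_0_mol
  structure(list(
    x = x, dx = dx,
    c_AI = rep(0, Nx),
    c_H2O = cW,
    Gamma = st$Gamma, r_p = st$r_p, eps = st$eps,
    D_AI = st$D_AI, D_H2O = st$D_H2O,
    c_AI_surface = c_surf,
    c_H2O_surface = (1 - p$v_bar_AI * c_surf) / p$v_bar_H2O,
    c_H2O_bath = d$c_H2O_pure
  ), class = "cuticle_field")
}

# Finite-volume right-hand side for the two conserved fields on the
# node-centred grid.  qA = eps * c_AI is evolved directly (its equation
# is already in conservation form); water is evolved as cW with the
# chain-rule capacity from pore_state().  Dirichlet values are imposed at
# half-cell distance through boundary faces; face diffusivities are
# arithmetic averages.  Returns time derivatives and the boundary-face
# fluxes of qA and qW (positive in +x, i.e. from droplet towards bath).
#
# bc: list(c_AI_surface, c_H2O_surface, ai_flux_closed = FALSE)
field_rhs <- function(qA, cW, bc, p, d, frozen_state = NULL) {
  Nx <- length(qA)
  dx <- p$b / Nx
  st <- if (is.null(frozen_state)) pore_state(cW, p, d) else frozen_state

  # boundary-adjacent pore state from the Dirichlet water values
  st0 <- if (is.null(frozen_state)) {
    pore_state(bc$c_H2O_surface, p, d)
  } else {
    lapply(frozen_state, function(v) v[1L])
  }
  stb <- if (is.null(frozen_state)) {
    pore_state(d$c_H2O_pure, p, d)
  } else {
    lapply(frozen_state, function(v) v[Nx])
  }

  # solute: conserved variable qA = eps * c_AI
  qA0 <- st0$eps * bc$c_AI_surface        # droplet-side Dirichlet
  qAb <- 0                                # well-stirred bath
  DA_face <- c((st0$D_AI + st$D_AI[1L]) / 2,
               (st$D_AI[-Nx] + st$D_AI[-1L]) / 2,
               (st$D_AI[Nx] + stb$D_AI) / 2)
  # fluxes F = -D dq/dx at the Nx + 1 faces
  FA <- numeric(Nx + 1L)
  FA[1L] <- if (isTRUE(bc$ai_flux_closed)) 0 else
    -DA_face[1L] * (qA[1L] - qA0) / (dx / 2)
  FA[2:Nx] <- -DA_face[2:Nx] * diff(qA) / dx
  FA[Nx + 1L] <- -DA_face[Nx + 1L] * (qAb - qA[Nx]) / (dx / 2)
  dqA <- -diff(FA) / dx

  # water: conserved variable qW = eps * cW, capacity form for cW
  qW <- st$eps * cW
  qW0 <- st0$eps * bc$c_H2O_surface
  qWb <- stb$eps * d$c_H2O_pure
  DW_face <- c((st0$D_H2O + st$D_H2O[1L]) / 2,
               (st$D_H2O[-Nx] + st$D_H2O[-1L]) / 2,
               (st$D_H2O[Nx] + stb$D_H2O) / 2)
  FW <- numeric(Nx + 1L)
  FW[1L] <- -DW_face[1L] * (qW[1L] - qW0) / (dx / 2)
  FW[2:Nx] <- -DW_face[2:Nx] * diff(qW) / dx
  FW[Nx + 1L] <- -DW_face[Nx + 1L] * (qWb - qW[Nx]) / (dx / 2)
  dcW <- -diff(FW) / dx / st$capacity

  list(dqA = dqA, dcW = dcW,
       flux_AI_surface = FA[1L], flux_AI_bath = FA[Nx + 1L],
       flux_H2O_surface = FW[1L],
       state = st)
}
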