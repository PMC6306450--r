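#' Angle unit conversion
#'
#' Angles are radians internally and degrees at interfaces.
#'
#' @param deg,rad angle in degrees / radians.
#' @return converted angle.
#' @export
deg2rad <- function(deg) deg * pi / 180

#' @rdname deg2rad
#' @export
rad2deg <- function(rad) rad * 180 / pi

#' Measured initial droplet contact data for CaCl2 on tomato fruit cuticle
#'
#' Initial contact areas of 1 uL droplets of CaCl2 solution deposited on
#' isolated astomatous tomato fruit cuticles, with and without the
#' ethoxylated rapeseed-oil surfactant RSO 5, together with the initial
#' contact angles back-calculated from spherical-cap geometry and the
#' receding angles (12.64 % below the initial angle).
#'
#' @return A data frame with columns `surfactant` (logical), `conc_gL`,
#'   `area_m2`, `theta0_deg`, `theta_rec_deg`.
#' @export
#' @examples
#' contact_angle_presets()
contact_angle_presets <- function() {
  data.frame(
    surfactant = rep(c(FALSE, TRUE), each = 5L),
    conc_gL = rep(c(1, 5, 10, 15, 30), 2L),
    area_m2 = c(0.49e-6, 0.84e-6, 0.86e-6, 0.57e-6, 0.55e-6,
                1.99e-6, 2.15e-6, 2.15e-6, 2.10e-6, 2.18e-6),
    theta0_deg = c(141.00, 126.58, 125.82, 137.50, 138.36,
                   87.91, 83.32, 83.32, 84.73, 82.48),
    theta_rec_deg = c(123.18, 110.58, 109.91, 120.12, 120.87,
                      76.79, 72.79, 72.79, 74.02, 72.06)
  )
}

#' Deliquescence properties of a hygroscopic active ingredient
#'
#' A hygroscopic material bundles the point of deliquescence (POD) with
#' the two empirical water-uptake functions needed by the evaporation
#' model: the final solution weight percentage `c_mass_pct(Phi)` and the
#' equilibrium water-to-solute mass ratio `m_inf(Phi)`, both functions of
#' the shifted relative humidity `Phi` (a fraction).  The built-in
#' material is CaCl2, fitted to published moisture-absorption data as a
#' sum of two exponentials; a different salt or formulation supplies its
#' own coefficient sets.
#'
#' @param POD point of deliquescence of the pure solute, RH fraction.
#' @param cmass_coef,minf_coef numeric vectors `c(a1, b1, a2, b2)` giving
#'   `a1*exp(b1*Phi) + a2*exp(b2*Phi)` for the weight-percent and
#'   water-uptake fits respectively.
#' @param name material label.
#' @return An object of class `hygro_material`: a list with fields `name`,
#'   `POD`, `cmass_coef`, `minf_coef` and vectorised functions
#'   `c_mass_pct(Phi)`, `m_inf(Phi)`.
#' @export
#' @examples
#' mat <- hygro_material()           # CaCl2
#' mat$m_inf(0.95)                   # about 14 g water per g CaCl2
hygro_material <- function(POD = 0.32,
                           cmass_coef = c(-0.8307, 3.618, 55.44, -0.612),
                           minf_coef = c(0.307, 2.763, 1.218e-9, 24),
                           name = "CaCl2") {
  stopifnot(POD >= 0, POD < 1, length(cmass_coef) == 4L, length(minf_coef) == 4L)
  two_exp <- function(coef) {
    force(coef)
    function(Phi) coef[1L] * exp(coef[2L] * Phi) + coef[3L] * exp(coef[4L] * Phi)
  }
  structure(
    list(name = name, POD = POD, cmass_coef = cmass_coef, minf_coef = minf_coef,
         c_mass_pct = two_exp(cmass_coef), m_inf = two_exp(minf_coef)),
    class = "hygro_material"
  )
}

# Fitted parameter sets (fractal dimension, ion-binding rate, pore
# density, logistic evaporation constant).  "alt" is the alternative set
# that improves the surfactant-only fit at high applied mass.
.fitted_sets <- list(
  default = list(F_s = 1.203, k = 8.68e-16, eta_pore = 2.18e15, chi = 0.043),
  alt     = list(F_s = 1.138, k = 3.74e-15, eta_pore = 1.99e15, chi = 0.0023)
)

#' Model parameters for the cuticle penetration model
#'
#' Assembles and validates the full physical parameter set.  Defaults
#' describe 1 uL droplets of CaCl2 with the surfactant RSO 5 on isolated
#' tomato fruit cuticle at 20 degrees C and 70 % relative humidity; three
#' presets switch the surfactant and fitted-parameter combinations.
#'
#' All values are SI internally (metres, seconds, moles, kelvin); applied
#' concentration is accepted in g/L (`c_AI_0_gL`) or mol/m^3
#' (`c_AI_0_mol`) and angles in degrees at this interface.
#'
#' @param preset one of `"cacl2_rso5"` (CaCl2 + RSO 5, default fitted
#'   set), `"cacl2"` (no surfactant: `xi = 0`, no-surfactant contact
#'   angles), `"cacl2_rso5_alt"` (alternative fitted set).
#' @param c_AI_0_gL applied concentration in g/L; one of
#'   1, 5, 10, 15, 30 selects the matching measured contact angle unless
#'   `theta_0_deg` is given.
#' @param c_AI_0_mol applied concentration in mol/m^3 (overrides
#'   `c_AI_0_gL` if non-NULL).
#' @param theta_0_deg initial contact angle in degrees; default looked up
#'   from [contact_angle_presets()].
#' @param theta_rec_deg receding contact angle in degrees; default
#'   `theta_0_deg * (1 - theta_rec_fraction)`.
#' @param theta_rec_fraction relative reduction from the initial to the
#'   receding contact angle (default 0.1264).
#' @param ... overrides for any other stored field (see Details).
#' @details Stored fields and defaults: cuticle thickness `b` (1.87e-5 m),
#'   bulk diffusivities `D_AI_bulk` (7.93e-10), `D_H2O_bulk` (2.299e-9),
#'   vapour diffusivity `D_evap` (2.4e-5 m^2/s), relative humidity `H`
#'   (0.7), temperature `T` (293.15 K), saturated vapour pressure `P_v`
#'   (2338.8 Pa), gas constant `R_gas`, Avogadro constant `N_A`, molar
#'   masses `M_w_AI` (110.98) and `M_w_H2O` (18.015 g/mol), densities
#'   `rho_AI` (2.16e6) and `rho_H2O` (9.98207e5 g/m^3), partial molar
#'   volumes `v_bar_AI` (1.6e-5) and `v_bar_H2O` (1.8047e-5 m^3/mol),
#'   water-molecule radius `r_H2O` (1.5e-10 m), maximum pore radius
#'   `r_p_max` (2.12e-9 m), initial pore-size reduction `gamma` (0.97),
#'   pore density `eta_pore`, fractal scaling dimension `F_s`, binding
#'   rate `k` (m^3/s), logistic decay constant `chi` (L^2/g^2), POD shift
#'   `xi` (RH fraction), initial volume `V_0` (1e-9 m^3), drop count
#'   `n_drops` (5), reference length `L` (1 m), control-volume area `A_Pi`
#'   (NULL: derived as `L^2 / (eta_pore * L^2 + 1)`), `t_final` (48 h in
#'   seconds), grid size `N_x` (100), `beta_H2O_override` (NULL: the
#'   Langmuir parameter is computed from the initial condition), and
#'   `material` (a [hygro_material()]).
#' @return A validated list of class `cuticle_params`.
#' @seealso [derive_constants()], [load_config()]
#' @export
#' @examples
#' p <- cuticle_params()                      # 1 g/L CaCl2 + RSO 5
#' p$theta_0                                  # 87.91 degrees, in radians
#' p30 <- cuticle_params(c_AI_0_gL = 30)      # matched contact angle
cuticle_params <- function(preset = c("cacl2_rso5", "cacl2", "cacl2_rso5_alt"),
                           c_AI_0_gL = 1,
                           c_AI_0_mol = NULL,
                           theta_0_deg = NULL,
                           theta_rec_deg = NULL,
                           theta_rec_fraction = 0.1264,
                           ...) {
  preset <- match.arg(preset)
  surfactant <- preset != "cacl2"
  fitted <- if (preset == "cacl2_rso5_alt") .fitted_sets$alt else .fitted_sets$default

  p <- list(
    preset = preset,
    surfactant = surfactant,
    b = 1.87e-5,
    D_AI_bulk = 7.93e-10,
    D_H2O_bulk = 2.299e-9,
    D_evap = 2.4e-5,
    H = 0.7,
    T = 293.15,
    P_v = 2338.8,
    R_gas = 8.3145,
    N_A = 6.02214e23,
    M_w_AI = 110.98,
    M_w_H2O = 18.015,
    rho_AI = 2.16e6,
    rho_H2O = 9.98207e5,
    v_bar_AI = 1.6e-5,
    v_bar_H2O = 1.8047e-5,
    r_H2O = 1.5e-10,
    r_p_max = 2.12e-9,
    gamma = 0.97,
    eta_pore = fitted$eta_pore,
    F_s = fitted$F_s,
    k = fitted$k,
    chi = fitted$chi,
    xi = if (surfactant) 0.05 else 0,
    V_0 = 1e-9,
    n_drops = 5L,
    L = 1,
    A_Pi = NULL,
    t_final = 48 * 3600,
    N_x = 100L,
    theta_rec_fraction = theta_rec_fraction,
    beta_H2O_override = NULL,
    material = hygro_material()
  )

  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown) > 0L)
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  p[names(dots)] <- dots
  p$N_x <- as.integer(p$N_x)
  p$n_drops <- as.integer(p$n_drops)

  # applied concentration: g/L is the experimental unit, mol/m^3 internal
  if (!is.null(c_AI_0_mol)) {
    p$c_AI_0_mol <- c_AI_0_mol
    p$c_AI_0_gL <- c_AI_0_mol * p$M_w_AI / 1000
  } else {
    p$c_AI_0_gL <- c_AI_0_gL
    p$c_AI_0_mol <- 1000 * c_AI_0_gL / p$M_w_AI
  }

  if (is.null(theta_0_deg)) {
    tab <- contact_angle_presets()
    row <- tab[tab$surfactant == surfactant &
                 abs(tab$conc_gL - p$c_AI_0_gL) < 1e-9, ]
    if (nrow(row) != 1L)
      stop("no measured contact angle for ", p$c_AI_0_gL,
           " g/L (surfactant = ", surfactant, "); supply theta_0_deg")
    theta_0_deg <- row$theta0_deg
  }
  p$theta_0 <- deg2rad(theta_0_deg)
  p$theta_rec <- if (is.null(theta_rec_deg)) {
    p$theta_0 * (1 - p$theta_rec_fraction)
  } else {
    deg2rad(theta_rec_deg)
  }

  validate_params(p)
  class(p) <- "cuticle_params"
  p
}

#' Validate a cuticle parameter set
#'
#' Checks the physical invariants of the parameter set: positivity of
#' densities, diffusivities and molar masses, `1 < F_s < 2`,
#' `0 <= H <= 1`, `0 < gamma <= 1`, `0 < theta_rec < theta_0 < pi`,
#' `r_H2O < r_p_max`, `V_0 > 0` and a porosity below one.
#'
#' @param p a parameter list as built by [cuticle_params()].
#' @return `p`, invisibly; errors on any violated invariant.
#' @export
validate_params <- function(p) {
  chk <- function(cond, msg) if (!isTRUE(cond)) stop("invalid parameters: ", msg)
  pos <- c("b", "D_AI_bulk", "D_H2O_bulk", "D_evap", "T", "P_v", "M_w_AI",
           "M_w_H2O", "rho_AI", "rho_H2O", "v_bar_AI", "v_bar_H2O",
           "r_H2O", "r_p_max", "eta_pore", "V_0", "L")
  for (nm in pos) chk(is.numeric(p[[nm]]) && p[[nm]] > 0, paste(nm, "must be > 0"))
  chk(p$F_s > 1 && p$F_s < 2, "F_s must satisfy 1 < F_s < 2")
  chk(p$H >= 0 && p$H <= 1, "H must lie in [0, 1]")
  chk(p$xi >= 0 && p$xi <= 1, "xi must lie in [0, 1]")
  chk(p$gamma > 0 && p$gamma <= 1, "gamma must lie in (0, 1]")
  chk(p$k >= 0, "k must be >= 0")
  chk(p$chi >= 0, "chi must be >= 0")
  chk(p$r_H2O < p$r_p_max, "r_H2O must be smaller than r_p_max")
  chk(p$theta_0 > 0 && p$theta_0 < pi, "theta_0 must lie in (0, pi)")
  chk(p$theta_rec > 0 && p$theta_rec < p$theta_0,
      "theta_rec must lie in (0, theta_0)")
  chk(p$N_x >= 10, "N_x must be at least 10")
  chk(p$t_final > 0, "t_final must be > 0")
  chk(p$n_drops >= 1, "n_drops must be >= 1")
  eps_max <- (p$eta_pore * p$L^2 + 1) * pi * p$r_p_max^2 / p$L^2
  chk(eps_max < 1, "pore density x maximum pore area exceeds the surface")
  chk(inherits(p$material, "hygro_material"), "material must be a hygro_material")
  invisible(p)
}

#' Constants derived from the primary parameter set
#'
#' Computes, from a validated parameter set: the saturated vapour
#' concentration deficit `psi = M_w_H2O * P_v * (1 - H) / (R * T)` (g/m^3),
#' the evaporation constant `Lambda = D_evap * psi / rho_H2O` (m^2/s), the
#' pure-water molar concentration `c_H2O_pure = rho_H2O / M_w_H2O`
#' (mol/m^3), the Langmuir saturation density `Gamma_S` (the adsorbed
#' density at which the pore reaches its maximum radius), the Langmuir
#' equilibrium parameter `beta_H2O` fixed so that the isotherm evaluated
#' at the initial interior water concentration reproduces the initial
#' adsorbed density of a pore at `gamma * r_p_max`, the concentration-
#' scaled logistic decay term `chi_bar = chi * c_AI_0_gL^2`, and the
#' receding time `t_rec` obtained by quadrature of the constant-contact-
#' radius angle equation.
#'
#' @param p a [cuticle_params()] object.
#' @param t_rec logical; also compute the receding-time quadrature
#'   (requires the evaporation kernel; set `FALSE` to skip).
#' @return A list of class `cuticle_derived` with fields `psi`, `Lambda`,
#'   `c_H2O_pure`, `Gamma_S`, `Gamma_0`, `beta_H2O`, `chi_bar`, `eps_0`,
#'   `r_drop_0`, `A_drop_0` and (optionally) `t_rec` (seconds).
#' @export
#' @examples
#' d <- derive_constants(cuticle_params(), t_rec = FALSE)
#' d$c_H2O_pure   # 55409.78 mol/m^3
derive_constants <- function(p, t_rec = TRUE) {
  validate_params(p)
  psi <- p$M_w_H2O * p$P_v * (1 - p$H) / (p$R_gas * p$T)
  Lambda <- p$D_evap * psi / p$rho_H2O
  c_pure <- p$rho_H2O / p$M_w_H2O

  Gamma_S <- gamma_from_pore_radius(p$r_p_max, p)
  Gamma_0 <- gamma_from_pore_radius(p$gamma * p$r_p_max, p)
  beta <- if (!is.null(p$beta_H2O_override)) {
    p$beta_H2O_override
  } else {
    # Langmuir parameter pinned to the initial condition: the isotherm at
    # the pure-water interior concentration must return Gamma_0 exactly
    1 / (c_pure * (Gamma_S / Gamma_0 - 1))
  }

  cap0 <- cap_from_volume(p$V_0, p$theta_0)
  d <- list(
    psi = psi,
    Lambda = Lambda,
    c_H2O_pure = c_pure,
    Gamma_S = Gamma_S,
    Gamma_0 = Gamma_0,
    beta_H2O = beta,
    chi_bar = p$chi * p$c_AI_0_gL^2,
    eps_0 = porosity(p$gamma * p$r_p_max, p),
    A_Pi = if (is.null(p$A_Pi)) p$L^2 / (p$eta_pore * p$L^2 + 1) else p$A_Pi,
    r_drop_0 = cap0$r_drop,
    A_drop_0 = cap0$A_drop
  )
  if (t_rec) {
    d$t_rec <- if (Lambda > 0) {
      t_rec_quadrature(p$theta_0, p$theta_rec, d$r_drop_0, Lambda)
    } else {
      Inf
    }
  }
  class(d) <- "cuticle_derived"
  d
}

#' Read a model configuration from YAML or JSON
#'
#' Keys are the parameter names of [cuticle_params()] (ASCII
#' transliterations of the model symbols: `eta_pore`, `F_s`, `chi`, `xi`,
#' ...).  Missing keys fall back to the preset defaults; `preset` itself
#' may be given in the file.  The applied concentration may be supplied
#' as `c_AI_0_gL` (g/L) or `c_AI_0_mol` (mol/m^3); any g/L-to-mol/m^3
#' conversion is recorded in the returned provenance attribute.  A
#' `material` key with fields `POD`, `cmass_coef`, `minf_coef`, `name`
#' replaces the built-in CaCl2 deliquescence data.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return A `cuticle_params` object with attribute `"provenance"`, a
#'   character vector logging applied overrides and unit conversions.
#' @seealso [write_config()]
#' @export
load_config <- function(path) {
  stopifnot(file.exists(path))
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (is.null(cfg)) cfg <- list()
  # JSON/YAML readers return whole numbers as integers; all physical
  # fields are doubles (grid size and drop count stay integral)
  for (nm in setdiff(names(cfg), c("N_x", "n_drops", "material")))
    if (is.integer(cfg[[nm]])) cfg[[nm]] <- as.double(cfg[[nm]])

  prov <- character(0)
  preset <- cfg$preset %||% "cacl2_rso5"
  cfg$preset <- NULL

  mat <- NULL
  if (!is.null(cfg$material)) {
    m <- cfg$material
    mat <- hygro_material(POD = m$POD %||% 0.32,
                          cmass_coef = as.numeric(m$cmass_coef),
                          minf_coef = as.numeric(m$minf_coef),
                          name = m$name %||% "custom")
    cfg$material <- NULL
    prov <- c(prov, sprintf("material: %s (POD = %.3f)", mat$name, mat$POD))
  }

  ctor_args <- c("c_AI_0_gL", "c_AI_0_mol", "theta_0_deg", "theta_rec_deg",
                 "theta_rec_fraction")
  known <- c(ctor_args, names(cuticle_params(preset = preset)))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0L)
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))

  args <- cfg[intersect(names(cfg), ctor_args)]
  extra <- cfg[setdiff(names(cfg), c(ctor_args, "preset", "surfactant",
                                     "c_AI_0_gL", "c_AI_0_mol",
                                     "theta_0", "theta_rec"))]
  if (!is.null(mat)) extra$material <- mat
  p <- do.call(cuticle_params, c(list(preset = preset), args, extra))

  if (!is.null(args$c_AI_0_gL))
    prov <- c(prov, sprintf("c_AI_0: %g g/L -> %.6g mol/m^3 via M_w_AI = %g g/mol",
                            p$c_AI_0_gL, p$c_AI_0_mol, p$M_w_AI))
  for (nm in setdiff(names(cfg), c(ctor_args)))
    prov <- c(prov, sprintf("override: %s", nm))
  attr(p, "provenance") <- prov
  p
}

#' Write a model configuration to YAML or JSON
#'
#' Serialises every scalar field of the parameter set (plus the material
#' coefficients) so that [load_config()] reproduces the object.  JSON
#' output keeps full double precision and round-trips bit-identically.
#'
#' @param p a `cuticle_params` object.
#' @param path output path ending in `.yaml`, `.yml` or `.json`.
#' @return `path`, invisibly.
#' @export
write_config <- function(p, path) {
  validate_params(p)
  out <- unclass(p)
  out$material <- list(name = p$material$name, POD = p$material$POD,
                       cmass_coef = p$material$cmass_coef,
                       minf_coef = p$material$minf_coef)
  out$theta_0_deg <- rad2deg(p$theta_0)
  out$theta_rec_deg <- rad2deg(p$theta_rec)
  out$theta_0 <- NULL
  out$theta_rec <- NULL
  out$c_AI_0_mol <- NULL      # derived from c_AI_0_gL on load
  out$surfactant <- NULL      # implied by preset
  out <- out[!vapply(out, is.null, logical(1))]
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(out, path, precision = 17L)
  } else {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cuticle_params <- function(x, ...) {
  cat("<cuticle_params> preset:", x$preset,
      "| c_AI_0:", format(x$c_AI_0_gL), "g/L",
      sprintf("(%.3f mol/m^3)", x$c_AI_0_mol),
      "| H:", x$H, "| xi:", x$xi, "\n")
  cat(sprintf("  theta_0 = %.2f deg, theta_rec = %.2f deg, V_0 = %g m^3, %d drops\n",
              rad2deg(x$theta_0), rad2deg(x$theta_rec), x$V_0, x$n_drops))
  cat(sprintf("  fitted: F_s = %g, k = %g m^3/s, eta_pore = %g /m^2, chi = %g L^2/g^2\n",
              x$F_s, x$k, x$eta_pore, x$chi))
  invisible(x)
}
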