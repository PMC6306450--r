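test_that("pore radius and adsorbed density are mutual inverses", {
  p <- cuticle_params()
  GS <- gamma_from_pore_radius(p$r_p_max, p)
  expect_equal(GS, 9.6832e-4, tolerance = 1e-4)
  expect_equal(pore_radius_from_gamma(GS, p), p$r_p_max, tolerance = 1e-12)
  expect_equal(gamma_from_pore_radius(0.97 * p$r_p_max, p), 9.37e-4,
               tolerance = 1e-3)
  rp <- seq(1.1 * 2 * p$r_H2O, p$r_p_max, length.out = 25)
  expect_equal(pore_radius_from_gamma(gamma_from_pore_radius(rp, p), p), rp,
               tolerance = 1e-12)
  expect_true(all(diff(gamma_from_pore_radius(rp, p)) > 0))
  expect_error(gamma_from_pore_radius(2 * p$r_H2O, p), "r_p")
  expect_error(pore_radius_from_gamma(0, p), "Gamma")
})

test_that("porosity is the areal pore fraction with quadratic scaling", {
  p <- cuticle_params()
  expect_equal(porosity(p$r_p_max, p),
               (p$eta_pore + 1) * pi * p$r_p_max^2, tolerance = 1e-12)
  expect_equal(porosity(p$r_p_max, p), 0.0308, tolerance = 1e-2)
  expect_equal(porosity(p$r_p_max / 2, p) / porosity(p$r_p_max, p), 0.25,
               tolerance = 1e-12)
  # single pore: porosity collapses to one pore per reference area
  p1 <- cuticle_params(eta_pore = 1e-12)  # effectively n0 = 0
  expect_equal(porosity(2e-9, p1), pi * (2e-9)^2 / 1, tolerance = 1e-6)
})

test_that("fractal effective diffusivity has the right limits and value", {
  # F_s -> 1 degenerates to the classical porosity scaling
  expect_equal(effective_diffusivity(0.03, 7.93e-10, 1 + 1e-12),
               7.93e-10 * 0.03, tolerance = 1e-9)
  expect_equal(effective_diffusivity(0.0308, 7.93e-10, 1.203),
               7.93e-10 * 0.0308^(1.203 / 0.797), tolerance = 1e-12)
  expect_equal(effective_diffusivity(0.0308, 7.93e-10, 1.203), 4.2e-12,
               tolerance = 0.03)
  # decreasing in tortuosity, increasing in porosity, bounded by D_bulk
  expect_gt(effective_diffusivity(0.03, 1e-9, 1.2),
            effective_diffusivity(0.03, 1e-9, 1.5))
  expect_lt(effective_diffusivity(0.9, 1e-9, 1.2), 1e-9)
  # species-independence of the porosity factor
  r1 <- effective_diffusivity(0.02, 7.93e-10, 1.3) / 7.93e-10
  r2 <- effective_diffusivity(0.02, 2.299e-9, 1.3) / 2.299e-9
  expect_equal(r1, r2, tolerance = 1e-14)
})

test_that("Langmuir isotherm saturates and vanishes correctly", {
  expect_identical(langmuir_gamma(0, 5e-4, 1e-3), 0)
  expect_equal(langmuir_gamma(1e12, 5e-4, 1e-3), 1e-3, tolerance = 1e-8)
  c <- seq(0, 2e5, length.out = 100)
  G <- langmuir_gamma(c, 5e-4, 1e-3)
  expect_true(all(G >= 0 & G < 1e-3))
  expect_true(all(diff(G) > 0))
})

test_that("initial field satisfies the model initial conditions", {
  p <- cuticle_params()
  d <- derive_constants(p, t_rec = FALSE)
  f <- initialize_field(p, d)
  expect_length(f$x, p$N_x)
  expect_true(all(f$c_AI == 0))                       # clean interior
  expect_true(all(f$c_H2O == d$c_H2O_pure))           # hydrated interior
  expect_equal(unique(f$r_p), p$gamma * p$r_p_max, tolerance = 1e-12)
  expect_equal(unique(f$Gamma), d$Gamma_0, tolerance = 1e-12)
  expect_equal(f$c_AI_surface, p$c_AI_0_mol)
  # surface water displaced by the dissolved solute's partial molar volume
  expect_equal(f$c_H2O_surface,
               (1 - p$v_bar_AI * p$c_AI_0_mol) / p$v_bar_H2O,
               tolerance = 1e-12)
  expect_equal(f$c_H2O_surface, 55402.9, tolerance = 1e-4)
  # degenerate: no solute puts the surface at (almost exactly) pure water
  p0 <- cuticle_params(c_AI_0_mol = 0, theta_0_deg = 87.91)
  f0 <- initialize_field(p0)
  expect_equal(f0$c_H2O_surface, 1 / p$v_bar_H2O, tolerance = 1e-12)
  expect_equal(f0$c_H2O_surface, d$c_H2O_pure, tolerance = 1e-4)
  # all invariants hold at t = 0
  expect_true(all(f$eps > 0 & f$eps < 1))
  expect_true(all(f$Gamma < d$Gamma_S))
  expect_true(all(f$r_p <= p$r_p_max))
})

test_that("finite-volume scheme annihilates the linear steady profile", {
  p <- cuticle_params(N_x = 37L)   # deliberately odd grid
  d <- derive_constants(p, t_rec = FALSE)
  Nx <- p$N_x; dx <- p$b / Nx
  x <- (seq_len(Nx) - 0.5) * dx
  frozen <- lapply(cuticleflux:::pore_state(rep(d$c_H2O_pure, Nx), p, d),
                   function(v) rep(v[1L], Nx))
  # steady diffusion between Dirichlet values q0 and qb is the straight line
  q0 <- frozen$eps[1L] * p$c_AI_0_mol
  qA <- q0 * (1 - x / p$b)
  bc <- list(c_AI_surface = p$c_AI_0_mol, c_H2O_surface = d$c_H2O_pure)
  fr <- cuticleflux:::field_rhs(qA, rep(d$c_H2O_pure, Nx), bc, p, d,
                                frozen_state = frozen)
  expect_lt(max(abs(fr$dqA)) * p$b^2 / (frozen$D_AI[1L] * q0), 1e-10)
  # boundary fluxes of the linear profile agree to the same accuracy
  expect_equal(fr$flux_AI_surface, fr$flux_AI_bath, tolerance = 1e-12)
})

test_that("discrete solute balance: interior change equals boundary fluxes", {
  p <- cuticle_params(N_x = 24L)
  d <- derive_constants(p, t_rec = FALSE)
  Nx <- p$N_x; dx <- p$b / Nx
  set.seed(4)
  qA <- runif(Nx) * 0.02 * p$c_AI_0_mol
  cW <- d$c_H2O_pure * (1 - runif(Nx) * 1e-3)
  bc <- list(c_AI_surface = p$c_AI_0_mol,
             c_H2O_surface = 0.999 * d$c_H2O_pure)
  fr <- cuticleflux:::field_rhs(qA, cW, bc, p, d)
  lhs <- sum(fr$dqA) * dx
  rhs <- fr$flux_AI_surface - fr$flux_AI_bath
  expect_equal(lhs, rhs, tolerance = 1e-12)
  # uniform field with uniform porosity: zero interior flux divergence
  frozen <- lapply(cuticleflux:::pore_state(rep(d$c_H2O_pure, Nx), p, d),
                   function(v) rep(v[1L], Nx))
  qU <- rep(0.01 * p$c_AI_0_mol, Nx)
  bcU <- list(c_AI_surface = qU[1L] / frozen$eps[1L],
              c_H2O_surface = d$c_H2O_pure)
  frU <- cuticleflux:::field_rhs(qU, rep(d$c_H2O_pure, Nx), bcU, p, d,
                                 frozen_state = frozen)
  expect_lt(max(abs(frU$dqA[-Nx])), 1e-20)   # bath Dirichlet drives cell Nx
})
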