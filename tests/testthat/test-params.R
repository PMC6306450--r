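test_that("derived constants match hand-evaluated values", {
  p <- cuticle_params()
  d <- derive_constants(p, t_rec = FALSE)
  # psi = M_w * P_v * (1 - H) / (R T), Lambda = D_evap * psi / rho
  expect_equal(d$psi, 18.015 * 2338.8 * 0.3 / (8.3145 * 293.15),
               tolerance = 1e-12)
  expect_equal(d$Lambda, d$psi * 2.4e-5 / 9.98207e5, tolerance = 1e-12)
  expect_equal(d$psi, 5.186, tolerance = 1e-3)
  expect_equal(d$Lambda, 1.247e-10, tolerance = 1e-3)
  expect_equal(d$c_H2O_pure, 55409.78, tolerance = 1e-6)
  expect_equal(d$Gamma_S, 9.6832e-4, tolerance = 1e-4)
  # saturated air: no evaporation
  d1 <- derive_constants(cuticle_params(H = 1), t_rec = FALSE)
  expect_identical(d1$psi, 0)
  expect_identical(d1$Lambda, 0)
})

test_that("logistic decay term scales with the squared applied concentration", {
  expect_equal(derive_constants(cuticle_params(), t_rec = FALSE)$chi_bar, 0.043)
  expect_equal(derive_constants(cuticle_params(c_AI_0_gL = 30),
                                t_rec = FALSE)$chi_bar, 0.043 * 900)
  p0 <- cuticle_params(c_AI_0_mol = 0, theta_0_deg = 87.91)
  expect_identical(derive_constants(p0, t_rec = FALSE)$chi_bar, 0)
})

test_that("Langmuir initialisation is self-consistent", {
  p <- cuticle_params()
  d <- derive_constants(p, t_rec = FALSE)
  # the isotherm at the pure-water interior concentration must reproduce
  # the adsorbed density of a pore at gamma * r_p_max exactly
  Gam <- langmuir_gamma(d$c_H2O_pure, d$beta_H2O, d$Gamma_S)
  expect_equal(Gam, gamma_from_pore_radius(p$gamma * p$r_p_max, p),
               tolerance = 1e-12)
  # and the printed-table value remains available as an override
  pov <- cuticle_params(beta_H2O_override = 3.77e-5)
  expect_equal(derive_constants(pov, t_rec = FALSE)$beta_H2O, 3.77e-5)
})

test_that("parameter invariants are enforced", {
  expect_error(cuticle_params(F_s = 2.5), "F_s")
  expect_error(cuticle_params(F_s = 1.0), "F_s")
  expect_error(cuticle_params(H = 1.3), "H")
  expect_error(cuticle_params(gamma = 0), "gamma")
  expect_error(cuticle_params(r_p_max = 1e-10), "r_H2O")
  expect_error(cuticle_params(theta_0_deg = 185), "theta_0")
  expect_error(cuticle_params(nonsense = 1), "unknown parameter")
  # pore density so high the pores exceed the available surface
  expect_error(cuticle_params(eta_pore = 1e17), "surface")
})

test_that("applied concentration unit conversion matches molar mass", {
  p <- cuticle_params(c_AI_0_gL = 1)
  expect_equal(p$c_AI_0_mol, 1000 / 110.98, tolerance = 1e-12)
  expect_equal(p$c_AI_0_mol, 9.01, tolerance = 2e-3)
  pm <- cuticle_params(c_AI_0_mol = 9.0104523, theta_0_deg = 88)
  expect_equal(pm$c_AI_0_gL, 9.0104523 * 110.98 / 1000, tolerance = 1e-12)
})

test_that("presets carry the measured contact angles and fitted sets", {
  p <- cuticle_params()
  expect_equal(rad2deg(p$theta_0), 87.91)
  expect_equal(rad2deg(p$theta_rec), 87.91 * (1 - 0.1264), tolerance = 1e-12)
  pn <- cuticle_params(preset = "cacl2", c_AI_0_gL = 1)
  expect_equal(rad2deg(pn$theta_0), 141.00)
  expect_identical(pn$xi, 0)
  pa <- cuticle_params(preset = "cacl2_rso5_alt")
  expect_equal(pa$F_s, 1.138)
  expect_equal(pa$k, 3.74e-15)
  expect_equal(pa$eta_pore, 1.99e15)
  expect_equal(pa$chi, 0.0023)
  # unmatched concentration without an explicit angle
  expect_error(cuticle_params(c_AI_0_gL = 7), "supply theta_0_deg")
})

test_that("empty config falls back to the default preset", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines("", f)
  p <- load_config(f)
  expect_equal(rad2deg(p$theta_0), 87.91)
  expect_equal(p$c_AI_0_gL, 1)
  expect_equal(p$H, 0.7)
})

test_that("config round-trips through JSON and YAML", {
  p <- cuticle_params(c_AI_0_gL = 10, H = 0.9, N_x = 60L,
                      chi = 0.01, xi = 0.03)
  for (ext in c(".json", ".yaml")) {
    f <- withr::local_tempfile(fileext = ext)
    write_config(p, f)
    q <- load_config(f)
    for (nm in c("b", "H", "xi", "chi", "F_s", "k", "eta_pore", "c_AI_0_gL",
                 "c_AI_0_mol", "V_0", "t_final", "N_x", "gamma", "r_p_max"))
      expect_identical(q[[nm]], p[[nm]], label = paste(ext, nm))
    # angles pass through a degree conversion at I/O (1 ulp tolerance)
    expect_equal(q$theta_0, p$theta_0, tolerance = 1e-14)
    expect_equal(q$theta_rec, p$theta_rec, tolerance = 1e-14)
  }
})

test_that("config provenance records unit conversions and overrides", {
  f <- withr::local_tempfile(fileext = ".json")
  writeLines('{"c_AI_0_gL": 5, "H": 0.9}', f)
  p <- load_config(f)
  expect_equal(p$c_AI_0_mol, 5000 / 110.98, tolerance = 1e-12)
  expect_equal(rad2deg(p$theta_0), 83.32)  # matched preset row
  prov <- attr(p, "provenance")
  expect_true(any(grepl("mol/m", prov)))
  expect_error(load_config({
    f2 <- withr::local_tempfile(fileext = ".json")
    writeLines('{"no_such_key": 1}', f2); f2
  }), "unknown configuration key")
})

test_that("custom hygroscopic material replaces the CaCl2 fits", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("material:",
               "  name: NaCl-like",
               "  POD: 0.75",
               "  cmass_coef: [0, 0, 26.0, -0.1]",
               "  minf_coef: [0.2, 3.0, 0, 0]"), f)
  p <- load_config(f)
  expect_equal(p$material$POD, 0.75)
  expect_equal(mass_percent(0.5, p$material), 26 * exp(-0.05))
  expect_false(shifted_humidity(p$H, p$xi, p$material$POD)$above_POD)
})
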