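# Dynamic behaviour of the coupled system, on a coarse grid for speed
# (N_x = 40; the acceptance suite exercises the default resolution).

coarse_run <- function() cached("coarse_default", {
  simulate_penetration(coarse_params())
})

test_that("mole audit closes at every output time", {
  sim <- coarse_run()
  rel <- max(abs(sim$audit$residual)) / sim$audit$applied[1L]
  expect_lt(rel, 1e-6)
  # every pool is physical
  expect_true(all(sim$audit$bound >= 0))
  expect_true(all(sim$audit$bath >= -1e-12 * sim$audit$applied[1L]))
  expect_true(all(diff(sim$audit$bound) >= -1e-12))
})

test_that("evaporation stages run CCR -> CCA -> frozen droplet, in order", {
  sim <- coarse_run()
  modes <- rle(sim$droplet$mode)$values
  expect_equal(modes, c("CCR", "CCA", "DRY"))
  expect_true(all(c("t_rec", "ai_exhausted") %in% names(sim$events)) ||
                all(c("t_rec", "dry_out") %in% names(sim$events)))
  expect_lt(sim$events[["t_rec"]], cessation_time_s(sim))
  # contact radius constant during CCR, then decreasing
  ccr <- sim$droplet$mode == "CCR"
  expect_equal(diff(range(sim$droplet$r_drop[ccr])), 0, tolerance = 1e-12)
  cca <- sim$droplet$mode == "CCA"
  expect_true(all(diff(sim$droplet$r_drop[cca]) < 1e-15))
  # angle pinned at theta_rec throughout CCA
  expect_equal(unique(sim$droplet$theta_deg[cca]),
               rad2deg(sim$params$theta_rec), tolerance = 1e-9)
})

test_that("penetration is monotone and consistent with the audit", {
  sim <- coarse_run()
  expect_true(all(diff(sim$penetration$pct) >= -1e-8))
  expect_true(all(sim$penetration$pct >= 0 & sim$penetration$pct <= 100))
  # m(t_final) equals applied - drop - bound - cuticle from the ledger
  last <- nrow(sim$audit)
  m_ledger <- with(sim$audit[last, ], applied - drop - bound - cuticle)
  expect_equal(tail(sim$penetration$m_ug, 1L),
               1e6 * sim$params$M_w_AI * m_ledger * sim$params$n_drops,
               tolerance = 1e-6)
})

test_that("quadrature of the bath-face flux reproduces the integrated mass", {
  sim <- coarse_run()
  m_quad <- penetration_mass(sim)
  expect_true(all(diff(m_quad) >= -1e-12))
  expect_equal(tail(m_quad, 1L), tail(sim$penetration$m_ug, 1L),
               tolerance = 5e-3)  # trapezoid on the output grid
  expect_equal(penetration_percent(tail(m_quad, 1L), sim$params),
               final_pct(sim), tolerance = 5e-3)
})

test_that("droplet shrinks while above its deliquescent volume", {
  sim <- coarse_run()
  cca <- sim$droplet$mode == "CCA"
  V <- sim$droplet$V[cca]; VD <- sim$droplet$V_Del[cca]
  above <- utils::head(V, -1) > utils::head(VD, -1) * 1.001
  expect_true(all(diff(V)[above] < 1e-18))
  # surface concentration stays below the crystallisation ceiling
  expect_true(all(sim$droplet$c_AI_surf <= sim$hygro$c_POD * (1 + 1e-6)))
})

test_that("swelling stays within the saturation bounds along the run", {
  sim <- coarse_run()
  expect_true(all(sim$field$Gamma < sim$derived$Gamma_S))
  expect_true(all(sim$field$r_p <= sim$params$r_p_max * (1 + 1e-9)))
  expect_true(all(sim$field$eps > 0 & sim$field$eps < 1))
  expect_true(all(sim$field$c_AI > -1e-8 * sim$params$c_AI_0_mol))
  expect_true(all(sim$field$c_H2O <= sim$derived$c_H2O_pure * (1 + 1e-9)))
})

test_that("penetration scales linearly in the number of drops", {
  p1 <- coarse_params(n_drops = 1L)
  p5 <- coarse_params(n_drops = 5L)
  s1 <- cached("coarse_1drop", simulate_penetration(p1))
  s5 <- coarse_run()
  expect_equal(tail(s5$penetration$m_ug, 1L) / tail(s1$penetration$m_ug, 1L),
               5, tolerance = 1e-9)
  # percent is per applied mass, hence identical
  expect_equal(final_pct(s5), final_pct(s1), tolerance = 1e-9)
})

test_that("the forward model is deterministic", {
  s1 <- coarse_run()
  s2 <- simulate_penetration(coarse_params())
  expect_identical(s1$penetration, s2$penetration)
  expect_identical(s1$droplet, s2$droplet)
  expect_identical(s1$events, s2$events)
})

test_that("solution is robust to tightening the tolerances", {
  s1 <- coarse_run()
  s2 <- cached("coarse_tight",
               simulate_penetration(coarse_params(), rtol = 5e-9, atol = 5e-13))
  expect_equal(final_pct(s2), final_pct(s1), tolerance = 1e-3)
  expect_equal(cessation_time_s(s2), cessation_time_s(s1), tolerance = 1e-3)
})

test_that("saturated air: no evaporation, angle stays pinned", {
  p <- coarse_params(H = 1, t_final = 2 * 3600)
  sim <- simulate_penetration(p)
  expect_false("t_rec" %in% names(sim$events))
  expect_true(all(sim$droplet$mode == "CCR"))
  expect_equal(diff(range(sim$droplet$V)), 0, tolerance = 1e-12 * p$V_0)
})

test_that("drop-limited regime: cuticle transit is much faster than depletion", {
  sim <- coarse_run()
  p <- sim$params; d <- sim$derived
  D_AI <- effective_diffusivity(d$eps_0, p$D_AI_bulk, p$F_s)
  t_transit <- p$b^2 / D_AI
  expect_lt(t_transit, 150)                   # seconds
  expect_gt(cessation_time_s(sim) / t_transit, 50)
})

test_that("CSV export writes the full result set", {
  sim <- coarse_run()
  dir <- withr::local_tempdir()
  write_sim_csv(sim, dir)
  expect_true(all(file.exists(file.path(dir, c("droplet.csv",
                                               "penetration.csv",
                                               "audit.csv", "events.json")))))
  pen <- utils::read.csv(file.path(dir, "penetration.csv"))
  expect_equal(nrow(pen), nrow(sim$penetration))
  expect_gt(length(list.files(dir, pattern = "^field_")), 3L)
})
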