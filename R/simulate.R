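# Assembly and integration of the coupled droplet/cuticle system.
#
# State vector (scaled to O(1) so uniform tolerances are meaningful):
#   1  V / V_0
#   2  theta (rad)
#   3  n_drop / n_applied          moles of solute in the droplet
#   4  m_bound / n_applied         cumulative surface-bound solute
#   5  N_cut / n_applied           flux-integrated solute in the cuticle
#   6  N_bath / n_applied          flux-integrated solute in the bath
#   7 .. 6+Nx        eps*c_AI / c_AI_0 per node
#   7+Nx .. 6+2Nx    c_H2O / c_H2O_pure per node
#
# The solute inventories are quadrature states: their derivatives sum to
# zero with the droplet and binding terms, so the mole audit closes to
# integrator accuracy at every output time.

.sim_context <- function(p, d, hygroscopic) {
  hs <- shifted_humidity(p$H, p$xi, p$material$POD)
  hygro_on <- switch(hygroscopic,
                     auto = hs$above_POD,
                     off = FALSE,
                     stop("hygroscopic must be 'auto' or 'off'"))
  # crystallisation ceiling for the non-deliquescent branch: at the POD
  # itself when the air is below the POD, at the shifted humidity when
  # deliquescence was switched off deliberately
  Phi_crys <- if (hs$above_POD) hs$Phi else p$material$POD
  list(
    p = p, d = d,
    Nx = as.integer(p$N_x),
    n_appl = p$c_AI_0_mol * p$V_0,
    hygro_on = hygro_on,
    above_POD = hs$above_POD,
    Phi = hs$Phi,
    c_POD = if (hs$above_POD) pod_concentration(hs$Phi, p) else NA_real_,
    m_inf_val = if (hs$above_POD) m_inf(hs$Phi, p$material) else NA_real_,
    c_crys = mass_percent(Phi_crys, p$material) * p$rho_AI / (100 * p$M_w_AI),
    f_fun = popov_f_interp(),
    f_rec = popov_f_interp()(p$theta_rec),
    g_rec = cap_g(p$theta_rec),
    S_scale = p$eta_pore * d$A_Pi,
    V_floor = 1e-9 * p$V_0,
    V_Del_floor = 1e-18,
    sV_dry = 1e-6,
    sn_dry = 1e-6
  )
}

.sim_rhs <- function(t, y, ctx, phase) {
  p <- ctx$p; d <- ctx$d; Nx <- ctx$Nx
  V <- y[1L] * p$V_0
  theta <- y[2L]
  n <- y[3L] * ctx$n_appl
  qA <- y[7:(6 + Nx)] * p$c_AI_0_mol
  cW <- y[(7 + Nx):(6 + 2 * Nx)] * d$c_H2O_pure

  dry <- phase == "dry"
  c_surf <- if (dry) 0 else max(n, 0) / max(V, ctx$V_floor)

  if (phase == "ccr") {
    r <- d$r_drop_0
  } else if (phase == "cca") {
    theta <- p$theta_rec
    r <- (3 * ctx$g_rec * max(V, 0) / pi)^(1 / 3)
  } else {
    r <- 0
  }
  A <- pi * r^2
  S <- ctx$S_scale * A

  bc <- list(
    c_AI_surface = c_surf,
    c_H2O_surface = if (dry) d$c_H2O_pure else
      max((1 - p$v_bar_AI * c_surf) / p$v_bar_H2O, 0.5 * d$c_H2O_pure),
    ai_flux_closed = dry
  )
  fr <- field_rhs(qA, cW, bc, p, d)

  if (dry) {
    dV <- 0; dtheta <- 0; dn <- 0; dbound <- 0; dcut <- 0; dbath <- 0
  } else {
    # droplet solute balance with the boundary-face flux from the scheme
    dn <- -p$k * c_surf - S * fr$flux_AI_surface
    dbound <- p$k * c_surf
    dcut <- S * (fr$flux_AI_surface - fr$flux_AI_bath)
    dbath <- S * fr$flux_AI_bath
    water_term <- -S * p$M_w_H2O / p$rho_H2O * fr$flux_H2O_surface

    if (phase == "ccr") {
      rr <- ccr_rates(theta, d$r_drop_0, d$Lambda, ctx$f_fun)
      dtheta <- rr$dtheta_dt
      dV <- rr$dV_dt
    } else {
      dtheta <- 0
      if (ctx$hygro_on) {
        V_Del <- ctx$m_inf_val * p$M_w_AI * max(n, 0) / p$rho_H2O
        dV <- cca_hygroscopic_rate(V, c_surf, V_Del, ctx$c_POD, p$theta_rec,
                                   d$Lambda, d$chi_bar, p$V_0,
                                   water_term, ctx$f_rec, ctx$V_Del_floor)
      } else {
        dV <- cca_below_pod_rate(V, p$theta_rec, d$Lambda, water_term,
                                 ctx$f_rec)
      }
    }
  }

  list(c(dV / p$V_0, dtheta,
         c(dn, dbound, dcut, dbath) / ctx$n_appl,
         fr$dqA / p$c_AI_0_mol,
         fr$dcW / d$c_H2O_pure))
}

.sim_root <- function(t, y, ctx, phase) {
  p <- ctx$p
  if (phase == "ccr") {
    c(y[2L] - p$theta_rec, y[1L] - ctx$sV_dry, y[3L] - ctx$sn_dry)
  } else if (ctx$hygro_on) {
    c(y[1L] - ctx$sV_dry, y[3L] - ctx$sn_dry)
  } else {
    c_surf <- max(y[3L] * ctx$n_appl, 0) / max(y[1L] * p$V_0, ctx$V_floor)
    c(y[1L] - ctx$sV_dry, y[3L] - ctx$sn_dry, c_surf - ctx$c_crys)
  }
}

.integrate_phase <- function(y0, t_from, t_grid, ctx, phase, rtol, atol) {
  times <- c(t_from, t_grid[t_grid > t_from])
  if (length(times) < 2L) times <- c(t_from, ctx$p$t_final)
  out <- if (phase == "dry") {
    # no events remain once the droplet is gone; BDF is robust for the
    # near-steady relaxation of the cuticle interior
    deSolve::vode(
      y = y0, times = times,
      func = function(t, y, parms) .sim_rhs(t, y, ctx, phase),
      parms = NULL, rtol = rtol, atol = atol, maxsteps = 50000
    )
  } else {
    deSolve::lsodar(
      y = y0, times = times,
      func = function(t, y, parms) .sim_rhs(t, y, ctx, phase),
      parms = NULL,
      rootfunc = function(t, y, parms) .sim_root(t, y, ctx, phase),
      rtol = rtol, atol = atol, maxsteps = 50000
    )
  }
  ist <- attr(out, "istate")
  if (!is.null(ist) && ist[1L] < 0)
    stop("cuticle simulation: integrator failed in ", phase,
         " phase (istate = ", ist[1L], ") at t = ",
         format(out[nrow(out), 1L]), " s")
  troot <- attr(out, "troot")
  list(out = out,
       troot = if (length(troot) > 0) troot else NULL,
       root_id = which(attr(out, "iroot") == 1L)[1L])
}

#' Run the coupled droplet-cuticle penetration model
#'
#' Integrates the full model from droplet deposition to `t_final`:
#' constant-contact-radius evaporation until the receding angle is
#' reached, then constant-contact-angle evaporation (with hygroscopic
#' deliquescent growth when the shifted humidity exceeds the solute POD),
#' coupled at every instant to solute and water diffusion through the
#' swelling aqueous pores of the cuticle, irreversible ion binding at the
#' surface, and the solute flux into the receiver bath.  After the
#' droplet dries out (or its solute is exhausted, or the solution
#' crystallises below the POD) the droplet state is frozen and the
#' cuticle interior continues to relax.
#'
#' @param p a [cuticle_params()] object.
#' @param hygroscopic `"auto"` (deliquescent growth whenever
#'   `H + xi > POD`) or `"off"` (bare evaporation in the de-pinned stage
#'   regardless of humidity, for mechanism isolation).
#' @param rtol,atol integration tolerances on the scaled state (defaults
#'   1e-8 and 1e-12).
#' @param n_out minimum number of output times over `[0, t_final]`; early
#'   times are refined since droplet dynamics are fastest in the first
#'   two hours.
#' @param n_snapshots number of cuticle field snapshots to retain.
#' @param strict if `TRUE`, violations of the state invariants (negative
#'   concentrations beyond round-off, adsorption above saturation) abort;
#'   otherwise they warn.
#' @return An object of class `cuticle_sim`: a list with elements
#'   `params`, `derived`, `hygro` (deliquescence state), `droplet` (time
#'   series of volume, angle, radius, area, surface concentration,
#'   deliquescent volume, mode), `penetration` (`t_h`, `m_ug`, `pct`),
#'   `audit` (mole ledger: applied, drop, bound, cuticle, bath, residual),
#'   `bath_flux` (bath-face flux series for the quadrature cross-check),
#'   `field` (snapshot matrices of `c_AI`, `c_H2O`, `Gamma`, `r_p`,
#'   `eps`), and `events` (named times in seconds).
#' @seealso [penetration_mass()], [penetration_percent()],
#'   [validation_suite()]
#' @export
#' @examples
#' \donttest{
#' p <- cuticle_params(N_x = 40L)   # coarse grid for a quick look
#' sim <- simulate_penetration(p)
#' tail(sim$penetration, 1)
#' }
simulate_penetration <- function(p, hygroscopic = c("auto", "off"),
                                 rtol = 1e-8, atol = 1e-12,
                                 n_out = 241L, n_snapshots = 25L,
                                 strict = FALSE) {
  hygroscopic <- match.arg(hygroscopic)
  validate_params(p)
  d <- derive_constants(p, t_rec = FALSE)
  ctx <- .sim_context(p, d, hygroscopic)
  Nx <- ctx$Nx
  tf <- p$t_final

  # output grid: dense early (droplet transients), even afterwards
  t_grid <- sort(unique(c(seq(0, min(2 * 3600, tf), length.out = 81L),
                          seq(0, tf, length.out = n_out))))

  field0 <- initialize_field(p, d)
  y <- c(1, p$theta_0, 1, 0, 0, 0,
         field0$eps * field0$c_AI / p$c_AI_0_mol,
         field0$c_H2O / d$c_H2O_pure)

  events <- numeric(0)
  rows <- list(); modes <- character(0)
  t_now <- 0
  # a pinned droplet stays in CCR until theta relaxes to theta_rec; in
  # saturated air that never happens and the drop remains pinned
  phase <- if (p$theta_0 > p$theta_rec) "ccr" else "cca"

  repeat {
    ph <- .integrate_phase(y, t_now, t_grid, ctx, phase, rtol, atol)
    out <- ph$out
    rows[[length(rows) + 1L]] <- out
    modes <- c(modes, rep(toupper(phase), nrow(out)))
    t_now <- out[nrow(out), 1L]
    y <- out[nrow(out), -1L]

    if (phase == "dry" || t_now >= tf * (1 - 1e-12)) break

    if (is.null(ph$troot)) {            # reached t_final without event
      break
    }
    root_id <- ph$root_id
    if (phase == "ccr") {
      if (root_id == 1L) {
        events["t_rec"] <- t_now
        phase <- "cca"
        y[2L] <- p$theta_rec
      } else {
        events[if (root_id == 2L) "dry_out" else "ai_exhausted"] <- t_now
        phase <- "dry"
      }
    } else {
      nm <- c("dry_out", "ai_exhausted", "crystallized")[root_id]
      events[nm] <- t_now
      phase <- "dry"
    }
  }

  full <- do.call(rbind, rows)
  keep <- !duplicated(full[, 1L], fromLast = TRUE)  # phase-boundary dupes
  full <- full[keep, , drop = FALSE]
  modes <- modes[keep]
  times <- full[, 1L]

  # unpack
  V <- full[, 2L] * p$V_0
  theta <- full[, 3L]
  n <- full[, 4L] * ctx$n_appl
  bound <- full[, 5L] * ctx$n_appl
  cut <- full[, 6L] * ctx$n_appl
  bath <- full[, 7L] * ctx$n_appl
  qA <- full[, 8:(7 + Nx), drop = FALSE] * p$c_AI_0_mol
  cW <- full[, (8 + Nx):(7 + 2 * Nx), drop = FALSE] * d$c_H2O_pure

  is_dry <- modes == "DRY"
  c_surf <- ifelse(is_dry, 0, pmax(n, 0) / pmax(V, ctx$V_floor))
  r_drop <- ifelse(modes == "CCR", d$r_drop_0,
                   (3 * ctx$g_rec * pmax(V, 0) / pi)^(1 / 3))
  r_drop[is_dry] <- 0
  theta_out <- ifelse(modes == "CCR", theta,
                      ifelse(is_dry, NA_real_, p$theta_rec))
  V_Del <- if (ctx$hygro_on) {
    ctx$m_inf_val * p$M_w_AI * pmax(n, 0) / p$rho_H2O
  } else {
    rep(NA_real_, length(times))
  }

  droplet <- data.frame(
    t_h = times / 3600, V = V, theta_deg = rad2deg(theta_out),
    r_drop = r_drop, A_drop = pi * r_drop^2,
    c_AI_surf = c_surf, V_Del = V_Del, mode = modes
  )

  pct <- bath / ctx$n_appl * 100
  penetration <- data.frame(
    t_h = times / 3600,
    m_ug = 1e6 * p$M_w_AI * bath * p$n_drops,
    pct = pct
  )

  audit <- data.frame(
    t_h = times / 3600,
    applied = ctx$n_appl, drop = n, bound = bound,
    cuticle = cut, bath = bath,
    residual = ctx$n_appl - (n + bound + cut + bath)
  )

  # bath-face flux series (per unit cuticle area, in the printed
  # convention D * d(eps c)/dx at x = b) for the quadrature cross-check
  dx <- p$b / Nx
  stb_D <- pore_state(d$c_H2O_pure, p, d)$D_AI
  DN <- pore_state(cW[, Nx], p, d)$D_AI
  D_face_b <- (DN + stb_D) / 2
  bath_flux <- data.frame(
    t = times,
    A_drop = pi * r_drop^2,
    D_dqdx_bath = D_face_b * (0 - qA[, Nx]) / (dx / 2)
  )

  snap_idx <- unique(round(seq(1L, length(times),
                               length.out = min(n_snapshots, length(times)))))
  snap_state <- pore_state(c(cW[snap_idx, , drop = FALSE]), p, d)
  dims <- c(length(snap_idx), Nx)
  field <- list(
    x = field0$x, t = times[snap_idx],
    c_AI = array(c(qA[snap_idx, , drop = FALSE]) /
                   array(snap_state$eps, dims), dims),
    c_H2O = cW[snap_idx, , drop = FALSE],
    Gamma = array(snap_state$Gamma, dims),
    r_p = array(snap_state$r_p, dims),
    eps = array(snap_state$eps, dims)
  )

  res <- structure(list(
    params = p, derived = d,
    hygro = list(above_POD = ctx$above_POD, Phi = ctx$Phi,
                 c_POD = ctx$c_POD, enabled = ctx$hygro_on),
    times = times, droplet = droplet, penetration = penetration,
    audit = audit, bath_flux = bath_flux, field = field,
    events = events
  ), class = "cuticle_sim")

  .check_invariants(res, strict)
  res
}

.check_invariants <- function(res, strict) {
  rel <- max(abs(res$audit$residual)) / res$audit$applied[1L]
  complain <- function(msg) if (strict) stop(msg) else warning(msg, call. = FALSE)
  if (rel > 1e-6)
    complain(sprintf("mole audit residual %.2e exceeds 1e-6 relative", rel))
  if (any(diff(res$penetration$pct) < -1e-8 * 100))
    complain("penetration percent decreased beyond round-off")
  GS <- res$derived$Gamma_S
  if (any(res$field$Gamma >= GS * (1 + 1e-9)))
    complain("adsorbed water exceeded the Langmuir saturation density")
  if (any(res$field$r_p > res$params$r_p_max * (1 + 1e-9)))
    complain("pore radius exceeded its maximum")
  invisible(res)
}

#' Cumulative penetration mass from the bath-face flux series
#'
#' Trapezoidal time integration of the solute flux through the inner
#' (bath) face of the cuticle, scaled to a mass:
#' `m(t) = -1e6 * M_w_AI * eta_pore * A_Pi * n_drops *
#' integral A_drop(t) (D_AI d(eps c_AI)/dx)|x=b dt` (micrograms).  This
#' recomputes, by quadrature over the stored output times, the same
#' quantity the simulator accumulates as an ODE state, and serves as its
#' cross-check.
#'
#' @param sim a `cuticle_sim` object (or a data frame with columns `t`,
#'   `A_drop`, `D_dqdx_bath`).
#' @param p parameters; taken from `sim` when omitted.
#' @return numeric vector of cumulative mass, micrograms, one per output
#'   time; non-decreasing.
#' @export
penetration_mass <- function(sim, p = NULL) {
  if (inherits(sim, "cuticle_sim")) {
    p <- sim$params
    flux <- sim$bath_flux
    d <- sim$derived
  } else {
    stopifnot(!is.null(p))
    flux <- sim
    d <- derive_constants(p, t_rec = FALSE)
  }
  integrand <- flux$A_drop * flux$D_dqdx_bath
  dt <- diff(flux$t)
  cum <- c(0, cumsum(dt * (utils::head(integrand, -1) +
                             utils::tail(integrand, -1)) / 2))
  -1e6 * p$M_w_AI * p$eta_pore * d$A_Pi * p$n_drops * cum
}

#' Percent penetration from a cumulative mass series
#'
#' `pct(t) = m(t) / (1e9 * c_AI_0_gL * n_drops * V_0) * 100`, the
#' penetrated fraction of the total applied solute mass (the applied
#' concentration enters in g/L).
#'
#' @param m_ug cumulative penetration mass, micrograms.
#' @param p a [cuticle_params()] object.
#' @return percent series.
#' @export
penetration_percent <- function(m_ug, p) {
  applied_ug <- 1e9 * p$c_AI_0_gL * p$n_drops * p$V_0
  if (applied_ug <= 0) stop("penetration_percent: no applied mass")
  m_ug / applied_ug * 100
}

#' @export
print.cuticle_sim <- function(x, ...) {
  fin <- utils::tail(x$penetration, 1L)
  cat(sprintf("<cuticle_sim> %s, c0 = %g g/L, H = %g, xi = %g\n",
              x$params$preset, x$params$c_AI_0_gL, x$params$H, x$params$xi))
  cat(sprintf("  final penetration: %.1f%% (%.3g ug) at %.1f h\n",
              fin$pct, fin$m_ug, fin$t_h))
  if (length(x$events) > 0)
    cat("  events:", paste(sprintf("%s = %.3f h", names(x$events),
                                   x$events / 3600), collapse = ", "), "\n")
  cat(sprintf("  mole audit |residual| <= %.2e relative\n",
              max(abs(x$audit$residual)) / x$audit$applied[1L]))
  invisible(x)
}

#' @export
plot.cuticle_sim <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  dr <- x$droplet
  graphics::plot(dr$t_h, dr$V * 1e9, type = "l", xlab = "time (h)",
                 ylab = "droplet water volume (uL)", main = "Evaporation")
  graphics::plot(dr$t_h, dr$c_AI_surf, type = "l", xlab = "time (h)",
                 ylab = "c_AI in drop (mol/m^3)", main = "Surface concentration")
  graphics::plot(dr$t_h, dr$r_drop * 1e3, type = "l", xlab = "time (h)",
                 ylab = "contact radius (mm)", main = "Contact radius")
  graphics::plot(x$penetration$t_h, x$penetration$pct, type = "l",
                 xlab = "time (h)", ylab = "% penetration",
                 main = "Penetration")
  invisible(x)
}

#' Export a simulation to CSV files
#'
#' Writes `droplet.csv`, `penetration.csv`, `audit.csv`,
#' `field_<hours>h.csv` (one per stored snapshot) and `events.json` under
#' `dir`.
#'
#' @param sim a `cuticle_sim` object.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_csv <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(sim$droplet, file.path(dir, "droplet.csv"),
                   row.names = FALSE)
  utils::write.csv(sim$penetration, file.path(dir, "penetration.csv"),
                   row.names = FALSE)
  utils::write.csv(sim$audit, file.path(dir, "audit.csv"), row.names = FALSE)
  for (i in seq_along(sim$field$t)) {
    df <- data.frame(x = sim$field$x,
                     c_AI = sim$field$c_AI[i, ],
                     c_H2O = sim$field$c_H2O[i, ],
                     Gamma = sim$field$Gamma[i, ],
                     r_p = sim$field$r_p[i, ],
                     eps = sim$field$eps[i, ])
    utils::write.csv(df, file.path(dir, sprintf("field_%.3fh.csv",
                                                sim$field$t[i] / 3600)),
                     row.names = FALSE)
  }
  jsonlite::write_json(as.list(sim$events), file.path(dir, "events.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
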