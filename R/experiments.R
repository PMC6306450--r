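# Scenario layer: validation suites across applied concentrations,
# one-factor-at-a-time sensitivity analysis, parameter estimation against
# penetration curves, curve characterisation and synthetic fixtures.

#' Validation suite across applied concentrations
#'
#' Runs the model at the five experimental applied concentrations (1, 5,
#' 10, 15, 30 g/L), each with its measured initial contact angle, with or
#' without the surfactant, and summarises the final percent penetration.
#' All runs share one fitted parameter set; only the applied
#' concentration and the contact angle differ between them.
#'
#' @param surfactant logical: include RSO 5 (POD shift `xi = 0.05` and
#'   the surfactant contact angles)?
#' @param p base parameters; concentration, contact angles and `xi` are
#'   replaced per run.
#' @param conc_gL concentrations to run, g/L (default the experimental
#'   five).
#' @param ... further arguments to [simulate_penetration()].
#' @return A list of class `validation_suite` with `runs` (named list of
#'   `cuticle_sim`), `summary` (data frame of final percent per
#'   concentration) and `mean_final_pct` / `sd_final_pct`.
#' @export
validation_suite <- function(surfactant = TRUE, p = NULL,
                             conc_gL = c(1, 5, 10, 15, 30), ...) {
  preset <- if (surfactant) "cacl2_rso5" else "cacl2"
  runs <- lapply(conc_gL, function(cc) {
    pc <- if (is.null(p)) {
      cuticle_params(preset = preset, c_AI_0_gL = cc)
    } else {
      # keep any overrides from p, replace the per-run fields
      do.call(cuticle_params,
              c(list(preset = preset, c_AI_0_gL = cc),
                p[setdiff(names(p),
                          c("preset", "surfactant", "c_AI_0_gL", "c_AI_0_mol",
                            "theta_0", "theta_rec", "xi"))]))
    }
    simulate_penetration(pc, ...)
  })
  names(runs) <- paste0(conc_gL, "g/L")
  fin <- vapply(runs, function(s) utils::tail(s$penetration$pct, 1L),
                numeric(1))
  structure(list(
    runs = runs,
    summary = data.frame(conc_gL = conc_gL, final_pct = fin),
    mean_final_pct = mean(fin),
    sd_final_pct = stats::sd(fin)
  ), class = "validation_suite")
}

#' @export
print.validation_suite <- function(x, ...) {
  cat("<validation_suite>\n")
  print(x$summary, row.names = FALSE)
  cat(sprintf("mean final penetration %.1f%% (SD %.1f)\n",
              x$mean_final_pct, x$sd_final_pct))
  invisible(x)
}

#' One-factor-at-a-time sensitivity analysis
#'
#' Perturbs parameters one at a time from a reference configuration and
#' quantifies the penetration response three ways: the percentage
#' relative sensitivity at the final time,
#' `S_pct = |d(final pct)/final pct| / |dp/p|`; the residual sum of
#' squares of the percent-penetration curve against the reference over
#' the common output grid, `S_SSres`; and its root-mean-square error,
#' `S_RMSE`.  Parameters are ranked by each measure (1 = most sensitive)
#' and labelled by the sign of the response (direct/inverse/nonmonotone).
#'
#' @param p reference parameters (the 1 g/L surfactant configuration at
#'   70 % RH is the usual baseline).
#' @param sweeps named list: for each parameter name, the perturbed
#'   values to run (reference value excluded automatically if present).
#' @param ... further arguments to [simulate_penetration()].
#' @return A list of class `sensitivity_oat` with `reference`
#'   (`cuticle_sim`), `detail` (one row per perturbed run) and `ranking`
#'   (one row per parameter with aggregated measures, ranks and
#'   proportionality).
#' @export
sensitivity_oat <- function(p, sweeps, ...) {
  stopifnot(is.list(sweeps), length(names(sweeps)) == length(sweeps))
  ref <- simulate_penetration(p, ...)
  ref_t <- ref$penetration$t_h
  ref_pct <- ref$penetration$pct
  ref_final <- utils::tail(ref_pct, 1L)

  detail <- list()
  for (nm in names(sweeps)) {
    ref_val <- if (nm == "theta_0") rad2deg(p$theta_0) else p[[nm]]
    if (is.null(ref_val)) stop("sensitivity_oat: unknown parameter ", nm)
    for (val in sweeps[[nm]]) {
      if (abs(val - ref_val) < 1e-12 * max(abs(ref_val), 1)) next
      pp <- p
      if (nm == "theta_0") {
        pp$theta_0 <- deg2rad(val)
        pp$theta_rec <- pp$theta_0 * (1 - pp$theta_rec_fraction)
      } else {
        pp[[nm]] <- val
        if (nm == "c_AI_0_gL") pp$c_AI_0_mol <- 1000 * val / pp$M_w_AI
      }
      sim <- tryCatch(simulate_penetration(pp, ...), error = function(e) e)
      if (inherits(sim, "error")) {
        warning("sensitivity_oat: ", nm, " = ", val, " skipped (",
                conditionMessage(sim), ")", call. = FALSE)
        next
      }
      pct <- stats::approx(sim$penetration$t_h, sim$penetration$pct,
                           xout = ref_t, rule = 2)$y
      fin <- utils::tail(sim$penetration$pct, 1L)
      dp_rel <- (val - ref_val) / ref_val
      detail[[length(detail) + 1L]] <- data.frame(
        parameter = nm, value = val, final_pct = fin,
        dp_rel = dp_rel,
        S_pct = abs((fin - ref_final) / ref_final) / abs(dp_rel),
        SS_res = sum((pct - ref_pct)^2),
        RMSE = sqrt(mean((pct - ref_pct)^2))
      )
    }
  }
  detail <- do.call(rbind, detail)
  if (is.null(detail) || nrow(detail) == 0L) {
    return(structure(list(reference = ref,
                          detail = data.frame(),
                          ranking = data.frame()),
                     class = "sensitivity_oat"))
  }

  agg <- do.call(rbind, lapply(split(detail, detail$parameter), function(df) {
    rho <- stats::cor(df$dp_rel, df$final_pct - ref_final)
    prop <- if (is.na(rho) || abs(rho) < 0.5) "nonmonotone" else
      if (rho > 0) "direct" else "inverse"
    data.frame(parameter = df$parameter[1L],
               S_pct = mean(df$S_pct), SS_res = mean(df$SS_res),
               RMSE = mean(df$RMSE), proportionality = prop)
  }))
  agg$rank_S_pct <- rank(-agg$S_pct, ties.method = "min")
  agg$rank_SS_res <- rank(-agg$SS_res, ties.method = "min")
  agg$rank_RMSE <- rank(-agg$RMSE, ties.method = "min")
  agg <- agg[order(agg$rank_S_pct), ]
  rownames(agg) <- NULL

  structure(list(reference = ref, detail = detail, ranking = agg),
            class = "sensitivity_oat")
}

#' @export
print.sensitivity_oat <- function(x, ...) {
  cat("<sensitivity_oat> reference final pct:",
      round(utils::tail(x$reference$penetration$pct, 1L), 2), "\n")
  print(x$ranking, row.names = FALSE)
  invisible(x)
}

#' Fit model parameters to penetration curves
#'
#' Nelder-Mead minimisation of the pooled squared residuals between the
#' simulated percent-penetration curve and one or more measured (or
#' synthetic) penetration datasets.  Free parameters are any subset of
#' the four fitted constants (`F_s`, `k`, `eta_pore`, `chi`), optimised
#' on transformed scales that enforce their bounds (`1 < F_s < 2` via a
#' logistic transform; the others log-positive).  With several datasets
#' the fit is staged as in the original calibration: a warm start on the
#' first dataset, then a joint fit over all of them with one shared
#' parameter set.
#'
#' @param datasets a `penetration_dataset` (from [make_fixture()] or
#'   [read_penetration_csv()]) or list of them.
#' @param free character vector naming the free parameters.
#' @param p base parameters; each dataset's `conc_gL`/`surfactant`
#'   metadata selects its applied concentration and contact angle.
#' @param start optional named list of starting values (defaults to the
#'   values in `p`).
#' @param control passed to [stats::optim()] (Nelder-Mead); sensible
#'   iteration caps are applied by default.
#' @param ... further arguments to [simulate_penetration()].
#' @return list of class `cuticle_fit`: `estimates` (named vector),
#'   `objective` (residual sum of squares), `r_squared` (per dataset),
#'   `converged` (logical flag from the optimiser), `stages`.
#' @export
fit_parameters <- function(datasets, free = c("k", "eta_pore"), p = NULL,
                           start = NULL, control = list(), ...) {
  if (inherits(datasets, "penetration_dataset")) datasets <- list(datasets)
  stopifnot(length(datasets) >= 1L,
            all(free %in% c("F_s", "k", "eta_pore", "chi")))
  if (is.null(p)) p <- cuticle_params()

  to_opt <- function(vals) {
    v <- numeric(length(free)); names(v) <- free
    for (nm in free) v[nm] <- if (nm == "F_s") stats::qlogis(vals[[nm]] - 1) else log(vals[[nm]])
    v
  }
  from_opt <- function(v) {
    out <- list()
    for (nm in free) out[[nm]] <- if (nm == "F_s") 1 + stats::plogis(v[[nm]]) else exp(v[[nm]])
    out
  }

  run_one <- function(pars, ds) {
    preset <- if (isTRUE(ds$surfactant)) "cacl2_rso5" else "cacl2"
    base <- p[setdiff(names(p), c("preset", "surfactant", "c_AI_0_gL",
                                  "c_AI_0_mol", "theta_0", "theta_rec"))]
    base[names(pars)] <- pars
    pc <- do.call(cuticle_params,
                  c(list(preset = preset, c_AI_0_gL = ds$conc_gL), base))
    sim <- simulate_penetration(pc, ...)
    stats::approx(sim$penetration$t_h, sim$penetration$pct,
                  xout = ds$data$t_h, rule = 2)$y
  }
  objective <- function(v, dss) {
    pars <- from_opt(v)
    sum(vapply(dss, function(ds) {
      pred <- tryCatch(run_one(pars, ds), error = function(e) NA_real_)
      if (anyNA(pred)) return(1e8)
      sum((pred - ds$data$pct)^2)
    }, numeric(1)))
  }

  ctrl <- utils::modifyList(list(maxit = 60L, reltol = 1e-4), control)
  v0 <- to_opt(if (is.null(start)) p[free] else
    utils::modifyList(p[free], start[intersect(names(start), free)]))
  # Nelder-Mead is the calibration heuristic even for a single free
  # parameter; silence optim's advisory about the one-dimensional case
  nm_optim <- function(...) {
    if (length(free) == 1L) suppressWarnings(stats::optim(...)) else
      stats::optim(...)
  }

  stages <- list()
  if (length(datasets) > 1L) {
    warm <- nm_optim(v0, objective, dss = datasets[1L],
                     method = "Nelder-Mead",
                     control = utils::modifyList(ctrl, list(maxit = ctrl$maxit %/% 2L)))
    stages$warm <- from_opt(warm$par)
    v0 <- warm$par
  }
  opt <- nm_optim(v0, objective, dss = datasets, method = "Nelder-Mead",
                  control = ctrl)
  est <- from_opt(opt$par)
  stages$joint <- est

  r2 <- vapply(datasets, function(ds) {
    pred <- run_one(est, ds)
    1 - sum((pred - ds$data$pct)^2) /
      max(sum((ds$data$pct - mean(ds$data$pct))^2), .Machine$double.eps)
  }, numeric(1))

  structure(list(estimates = unlist(est), objective = opt$value,
                 r_squared = r2, converged = opt$convergence == 0L,
                 stages = stages),
            class = "cuticle_fit")
}

#' @export
print.cuticle_fit <- function(x, ...) {
  cat("<cuticle_fit>", if (x$converged) "converged" else
    "NOT converged (iteration cap)", "\n")
  print(x$estimates)
  cat("RSS:", format(x$objective), " R^2:",
      paste(round(x$r_squared, 3), collapse = ", "), "\n")
  invisible(x)
}

#' Two-timescale exponential characterisation of a penetration curve
#'
#' Fits `pct(t) = a1 (1 - exp(-t/tau1)) + a2 (1 - exp(-t/tau2))` by
#' nonlinear least squares, the standard diagnostic for penetration data
#' with an initial rapid phase followed by a slow approach to a plateau.
#' Reported with `tau1 < tau2`; well-separated timescales indicate at
#' least two distinct governing mechanisms.
#'
#' @param dataset a `penetration_dataset`, or a data frame with columns
#'   `t_h` and `pct` (at least 5 points).
#' @return list of class `two_exp_fit` with `coefficients`
#'   (`a1, tau1, a2, tau2`), `fitted`, `residuals`, `degenerate` (TRUE
#'   when the data carry no curvature and a single-exponential or flat
#'   fallback was used).
#' @export
two_exponential_fit <- function(dataset) {
  df <- if (inherits(dataset, "penetration_dataset")) dataset$data else dataset
  stopifnot(all(c("t_h", "pct") %in% names(df)), nrow(df) >= 5L)
  t <- df$t_h; y <- df$pct

  if (stats::sd(y) < 1e-10) {
    return(structure(list(
      coefficients = c(a1 = 0, tau1 = NA_real_, a2 = 0, tau2 = NA_real_),
      fitted = rep(mean(y), length(y)), residuals = y - mean(y),
      degenerate = TRUE), class = "two_exp_fit"))
  }

  span <- max(t[t > 0])
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ a1 * (1 - exp(-t / tau1)) + a2 * (1 - exp(-t / tau2)),
      start = list(a1 = max(y) / 2, tau1 = span / 20,
                   a2 = max(y) / 2, tau2 = span / 2),
      lower = c(0, 1e-6, 0, 1e-6), upper = c(200, 10 * span, 200, 10 * span),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)

  if (is.null(fit)) {
    # single-exponential fallback for degenerate shapes
    f1 <- minpack.lm::nlsLM(y ~ a * (1 - exp(-t / tau)),
                            start = list(a = max(y), tau = span / 5),
                            lower = c(0, 1e-6), upper = c(200, 10 * span))
    cf <- stats::coef(f1)
    return(structure(list(
      coefficients = c(a1 = unname(cf["a"]), tau1 = unname(cf["tau"]),
                       a2 = 0, tau2 = NA_real_),
      fitted = stats::fitted(f1), residuals = stats::resid(f1),
      degenerate = TRUE), class = "two_exp_fit"))
  }

  cf <- stats::coef(fit)
  if (cf[["tau1"]] > cf[["tau2"]])
    cf <- c(a1 = cf[["a2"]], tau1 = cf[["tau2"]],
            a2 = cf[["a1"]], tau2 = cf[["tau1"]])
  structure(list(
    coefficients = c(a1 = unname(cf[["a1"]]), tau1 = unname(cf[["tau1"]]),
                     a2 = unname(cf[["a2"]]), tau2 = unname(cf[["tau2"]])),
    fitted = stats::fitted(fit), residuals = stats::resid(fit),
    degenerate = FALSE), class = "two_exp_fit")
}

#' Synthetic penetration dataset from the model
#'
#' Runs the model and samples the percent-penetration curve at the assay
#' cadence of typical cuticle-penetration experiments, optionally adding
#' seeded Gaussian noise (clamped to `[0, 100]`).  Used as the
#' ground-truth fixture for parameter-recovery experiments in place of
#' figure-only experimental data.
#'
#' @param p model parameters.
#' @param noise_sd Gaussian noise standard deviation, percent points.
#' @param seed RNG seed (an integer; the dataset is reproducible).
#' @param times_h sampling times, hours.
#' @param ... further arguments to [simulate_penetration()].
#' @return A list of class `penetration_dataset`: `data` (data frame
#'   `t_h`, `pct`, `sd`), `conc_gL`, `surfactant`, `noise_sd`, `seed`.
#' @export
make_fixture <- function(p, noise_sd = 0, seed = 1L,
                         times_h = c(0.5, 1, 2, 4, 8, 24, 48), ...) {
  sim <- simulate_penetration(p, ...)
  pct <- stats::approx(sim$penetration$t_h, sim$penetration$pct,
                       xout = times_h, rule = 2)$y
  if (noise_sd > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    pct <- pmin(pmax(pct + stats::rnorm(length(pct), 0, noise_sd), 0), 100)
  }
  structure(list(
    data = data.frame(t_h = times_h, pct = pct, sd = noise_sd),
    conc_gL = p$c_AI_0_gL, surfactant = p$surfactant,
    noise_sd = noise_sd, seed = seed
  ), class = "penetration_dataset")
}

#' Read a digitised penetration curve from CSV
#'
#' Schema: columns `t_h` (hours, non-negative increasing), `pct`
#' (percent in `[0, 100]`) and optionally `sd`; metadata columns
#' `conc_gL` and `surfactant` may be supplied as arguments instead.
#'
#' @param path CSV file path.
#' @param conc_gL,surfactant dataset metadata.
#' @return A `penetration_dataset`.
#' @export
read_penetration_csv <- function(path, conc_gL = 1, surfactant = TRUE) {
  df <- utils::read.csv(path)
  stopifnot(all(c("t_h", "pct") %in% names(df)))
  if (is.unsorted(df$t_h, strictly = FALSE) || any(df$t_h < 0))
    stop("read_penetration_csv: t_h must be non-negative and increasing")
  if (any(df$pct < 0 | df$pct > 100))
    stop("read_penetration_csv: pct must lie in [0, 100]")
  if (is.null(df$sd)) df$sd <- NA_real_
  structure(list(data = df[, c("t_h", "pct", "sd")],
                 conc_gL = conc_gL, surfactant = surfactant,
                 noise_sd = NA_real_, seed = NA_integer_),
            class = "penetration_dataset")
}
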