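# Spherical-cap geometry and the diffusion-limited sessile-droplet
# evaporation kernel (Popov model).

#' Spherical-cap volume factor g(theta)
#'
#' `g(theta) = sin^3(theta) / ((1 - cos(theta))^2 (2 + cos(theta)))`,
#' the geometric factor linking the contact radius of a spherical cap to
#' its volume: `r_drop = (3 g(theta) V / pi)^(1/3)`.  Strictly decreasing
#' on (0, pi).
#'
#' @param theta contact angle in radians, in (0, pi); vectorised.
#' @return dimensionless positive scalar(s).
#' @export
#' @examples
#' cap_g(pi / 2)   # 0.5
cap_g <- function(theta) {
  if (any(theta <= 0 | theta >= pi))
    stop("cap_g: theta must lie strictly inside (0, pi)")
  sin(theta)^3 / ((1 - cos(theta))^2 * (2 + cos(theta)))
}

# Stable integrand of the Popov evaporation integral.  The naive form
# cosh^2(theta*u) * csch(2*pi*u) overflows for moderate u; rewritten with
# the common exponential factored out it decays like exp(-2*(pi-theta)*u).
.popov_integrand <- function(u, theta) {
  ifelse(u == 0,
         4 * (pi - theta) / pi,
         exp(2 * (theta - pi) * u) * (1 + exp(-2 * theta * u))^2 /
           (2 * (1 - exp(-4 * pi * u))) * 8 * tanh((pi - theta) * u))
}

#' Popov evaporation function f(theta)
#'
#' `f(theta) = tan(theta/2) + 8 * integral_0^inf cosh^2(theta u)
#' csch(2 pi u) tanh((pi - theta) u) du`, the angular factor of the
#' quasi-steady diffusion-limited evaporation rate of a sessile spherical
#' cap.  Evaluated by adaptive quadrature on a numerically stable form of
#' the integrand.  Closed-form limits: `f -> 4/pi` as `theta -> 0` (flat
#' disk) and `f(pi/2) = 2` (hemisphere).
#'
#' @param theta contact angle in radians, in `[0, pi)`; vectorised.
#' @param rel.tol quadrature relative tolerance.
#' @return dimensionless positive scalar(s).
#' @export
#' @examples
#' popov_f(0)        # 4 / pi
#' popov_f(pi / 2)   # 2
popov_f <- function(theta, rel.tol = 1e-10) {
  if (any(theta < 0 | theta >= pi))
    stop("popov_f: theta must lie in [0, pi)")
  vapply(theta, function(th) {
    if (rad2deg(th) > 150)
      warning("popov_f: evaporation kernel applied beyond its validated ",
              "range (theta > 150 deg)", call. = FALSE)
    quad <- stats::integrate(.popov_integrand, 0, Inf, theta = th,
                             rel.tol = rel.tol, stop.on.error = FALSE)
    if (!quad$message %in% "OK")
      stop("popov_f: quadrature failed at theta = ", format(th), ": ",
           quad$message)
    tan(th / 2) + quad$value
  }, numeric(1))
}

# Cached cubic-spline tabulation of f(theta) on a 0.1 degree grid.  f is
# evaluated inside every ODE right-hand side; direct quadrature there
# would dominate the run time.  Interpolation error is far below 1e-6
# over (0, 179 deg).
.cache <- new.env(parent = emptyenv())

popov_f_interp <- function() {
  if (is.null(.cache$popov_f_fun)) {
    grid <- deg2rad(seq(0, 179, by = 0.1))
    vals <- suppressWarnings(popov_f(grid, rel.tol = 1e-11))
    .cache$popov_f_fun <- stats::splinefun(grid, vals, method = "natural")
  }
  .cache$popov_f_fun
}

#' Spherical cap from water volume and contact angle
#'
#' Contact radius `r_drop = (3 g(theta) V / pi)^(1/3)`, contact area
#' `A_drop = pi^(1/3) (3 g(theta) V)^(2/3) = pi r_drop^2`, apex height and
#' full sphere radius `R_s = r_drop / sin(theta)`.
#'
#' @param V water volume, m^3 (`V >= 0`; zero yields a degenerate cap).
#' @param theta contact angle, radians, in (0, pi).
#' @return A list of class `spherical_cap` with `V`, `theta`, `r_drop`,
#'   `A_drop`, `h`, `R_s`.
#' @export
#' @examples
#' cap_from_volume(1e-9, 87.91 * pi / 180)$A_drop  # 1.99e-6 m^2
cap_from_volume <- function(V, theta) {
  if (any(V < 0)) stop("cap_from_volume: V must be >= 0")
  g <- cap_g(theta)
  r <- (3 * g * V / pi)^(1 / 3)
  structure(list(V = V, theta = theta, r_drop = r, A_drop = pi * r^2,
                 h = r * (1 - cos(theta)) / sin(theta),
                 R_s = ifelse(r > 0, r / sin(theta), 0)),
            class = "spherical_cap")
}

#' Initial contact angle from measured contact area and volume
#'
#' Inverts the spherical-cap area relation
#' `A = pi^(1/3) (3 g(theta) V)^(2/3)` for `theta` by bracketed
#' root-finding on (0.01, 179) degrees, the numerical counterpart of the
#' secant-method back-calculation used to obtain the measured initial
#' contact angles from droplet footprint areas.
#'
#' @param A_drop_0 measured initial contact area, m^2.
#' @param V_0 droplet volume, m^3.
#' @param tol relative tolerance on the recovered area (default 1e-10).
#' @return contact angle in radians.
#' @export
#' @examples
#' rad2deg(theta0_from_area(1.99e-6, 1e-9))   # 87.91 (RSO 5, 1 g/L)
#' rad2deg(theta0_from_area(0.49e-6, 1e-9))   # 141.00 (no surfactant)
theta0_from_area <- function(A_drop_0, V_0, tol = 1e-10) {
  stopifnot(A_drop_0 > 0, V_0 > 0)
  area <- function(th) pi^(1 / 3) * (3 * cap_g(th) * V_0)^(2 / 3)
  lo <- deg2rad(0.01); hi <- deg2rad(179)
  # area is strictly decreasing in theta
  if (A_drop_0 > area(lo) || A_drop_0 < area(hi))
    stop("theta0_from_area: no contact angle in (0.01, 179) degrees ",
         "matches this area/volume pair")
  root <- stats::uniroot(function(th) area(th) - A_drop_0, c(lo, hi),
                         tol = 1e-14)$root
  if (abs(area(root) - A_drop_0) / A_drop_0 > tol)
    stop("theta0_from_area: root finding did not reach requested tolerance")
  root
}

#' Receding contact angle
#'
#' The contact angle at which the contact line de-pins and evaporation
#' switches from constant-contact-radius to constant-contact-angle mode,
#' estimated as a fixed relative reduction of the initial angle
#' (`theta_rec = theta_0 * (1 - fraction)`; default reduction 12.64 %).
#'
#' @param theta_0 initial contact angle, radians.
#' @param fraction relative reduction in `[0, 1)`.
#' @return receding angle, radians.
#' @export
#' @examples
#' rad2deg(receding_angle(87.91 * pi / 180))   # 76.79
receding_angle <- function(theta_0, fraction = 0.1264) {
  stopifnot(fraction >= 0, fraction < 1)
  theta_0 * (1 - fraction)
}

#' Receding time by quadrature of the pinned-stage angle equation
#'
#' Integrates `t_rec = integral_{theta_rec}^{theta_0} r_0^2 /
#' (Lambda (1 + cos(theta))^2 f(theta)) dtheta`, the time for the contact
#' angle of a pinned droplet to fall from `theta_0` to `theta_rec`.  Used
#' as an independent cross-check of the event time found by the ODE
#' integration.
#'
#' @param theta_0,theta_rec initial and receding contact angles, radians.
#' @param r_drop_0 pinned contact radius, m.
#' @param Lambda evaporation constant, m^2/s.
#' @return time in seconds.
#' @export
t_rec_quadrature <- function(theta_0, theta_rec, r_drop_0, Lambda) {
  stopifnot(theta_rec < theta_0, Lambda > 0, r_drop_0 > 0)
  f <- popov_f_interp()
  stats::integrate(function(th) r_drop_0^2 / (Lambda * (1 + cos(th))^2 * f(th)),
                   theta_rec, theta_0, rel.tol = 1e-10)$value
}

#' Droplet cross-section profile
#'
#' Samples the spherical-cap surface of a droplet as (radius, height)
#' pairs, suitable for plotting evaporation-stage profiles or exporting
#' to CSV.
#'
#' @param cap a `spherical_cap` (from [cap_from_volume()]).
#' @param n number of sample points.
#' @return A data frame with columns `r` and `z` (metres), spanning the
#'   full cross-section from `-r_drop` to `r_drop`.
#' @export
droplet_profile <- function(cap, n = 181L) {
  if (cap$V <= 0 || cap$r_drop <= 0)
    return(data.frame(r = 0, z = 0))
  Rs <- cap$R_s
  zc <- -Rs * cos(cap$theta)       # sphere centre below/above the surface
  phi <- seq(-cap$theta, cap$theta, length.out = n)
  data.frame(r = Rs * sin(phi), z = zc + Rs * cos(phi))
}

#' @export
print.spherical_cap <- function(x, ...) {
  cat(sprintf("<spherical_cap> V = %.4g m^3, theta = %.2f deg, r = %.4g m, A = %.4g m^2\n",
              x$V, rad2deg(x$theta), x$r_drop, x$A_drop))
  invisible(x)
}
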