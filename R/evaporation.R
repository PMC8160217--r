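#' Contact-angle factor of diffusion-limited droplet evaporation
#'
#' Dimensionless factor \eqn{f(\theta)} multiplying \eqn{\pi R D (n_s -
#' n_\infty)} in the quasi-steady, diffusion-limited evaporation rate of a
#' sessile spherical-cap droplet:
#' \deqn{f(\theta) = \frac{\sin\theta}{1+\cos\theta} + 4\int_0^\infty
#'   \frac{1+\cosh 2\theta\tau}{\sinh 2\pi\tau}
#'   \tanh[(\pi-\theta)\tau]\,d\tau.}
#' Closed-form anchors: \eqn{f(\pi/2) = 2} (hemisphere) and
#' \eqn{f(\theta \to 0) = 4/\pi} (flat disk).
#'
#' The integrand has a finite limit \eqn{(\pi-\theta)/\pi} at \eqn{\tau = 0}
#' and decays like \eqn{e^{-2(\pi-\theta)\tau}}; for large \eqn{\tau} the
#' hyperbolic ratio is evaluated in its asymptotic exponential form to avoid
#' overflow.
#'
#' @param theta Contact angle(s) in rad, in (0, pi).
#' @param rel_tol Relative tolerance of the quadrature.
#' @return f(theta), dimensionless (vectorized over `theta`).
#' @examples
#' contact_angle_factor(pi / 2)   # 2
#' contact_angle_factor(1e-6)     # ~ 4/pi
#' @export
contact_angle_factor <- function(theta, rel_tol = 1e-9) {
  stopifnot(is.numeric(theta))
  if (any(!is.finite(theta) | theta <= 0 | theta >= pi))
    stop("`theta` must lie in (0, pi) rad")
  one <- function(th) {
    integrand <- function(tau) {
      out <- numeric(length(tau))
      tiny <- tau < 1e-12
      big <- tau >= 6
      mid <- !tiny & !big
      out[tiny] <- (pi - th) / pi
      out[mid] <- (1 + cosh(2 * th * tau[mid])) / sinh(2 * pi * tau[mid]) *
        tanh((pi - th) * tau[mid])
      # (1 + cosh x)/sinh y -> e^(x - y) for large arguments
      out[big] <- exp(2 * (th - pi) * tau[big]) * tanh((pi - th) * tau[big])
      out
    }
    q <- tryCatch(
      stats::integrate(integrand, 0, Inf, rel.tol = rel_tol,
                       abs.tol = 0, subdivisions = 500L),
      error = function(e)
        stop("contact-angle factor quadrature failed at theta = ", th,
             " rad: ", conditionMessage(e)))
    sin(th) / (1 + cos(th)) + 4 * q$value
  }
  vapply(theta, one, numeric(1))
}

#' Total evaporation rate of a sessile droplet
#'
#' Magnitude of the water-mass loss rate of a diffusion-limited evaporating
#' spherical-cap droplet, \eqn{|dM/dt| = \pi R D (n_s - n_\infty) f(\theta)}.
#'
#' @param geom A [droplet_geometry()].
#' @param ambient An [ambient_conditions()].
#' @return Evaporation rate in kg s^-1 (non-negative).
#' @export
total_evaporation_rate <- function(geom, ambient) {
  stopifnot(inherits(geom, "droplet_geometry"),
            inherits(ambient, "ambient_conditions"))
  dn <- ambient$saturated_vapor_concentration -
    ambient$ambient_vapor_concentration
  pi * geom$contact_radius * ambient$vapor_diffusivity * dn *
    contact_angle_factor(geom$contact_angle)
}

# normalization C of J(r) = C (R0 - r)^(-1/2):
# disk integral 2 pi C int_0^R0 r (R0-r)^(-1/2) dr = 2 pi C (4/3) R0^(3/2)
flux_prefactor <- function(geom, ambient) {
  rate <- total_evaporation_rate(geom, ambient)
  3 * rate / (8 * pi * geom$contact_radius^1.5)
}

#' Local evaporation flux with the edge singularity
#'
#' Edge-divergent evaporative mass flux \eqn{J(r) = C (R_0 - r)^{-1/2}},
#' normalized so the integral over the contact disk equals
#' [total_evaporation_rate()]. The inverse-square-root divergence at the
#' pinned contact line is integrable; the normalization integral is done
#' analytically.
#'
#' @inheritParams total_evaporation_rate
#' @param r Radial positions in m, `0 <= r < contact_radius`.
#' @return Flux J(r) in kg m^-2 s^-1.
#' @export
local_evaporation_flux <- function(r, geom, ambient) {
  stopifnot(inherits(geom, "droplet_geometry"), is.numeric(r))
  R0 <- geom$contact_radius
  if (any(r < 0 | r >= R0))
    stop("`r` must lie in [0, contact_radius); the contact line itself is ",
         "a singular point of the flux")
  flux_prefactor(geom, ambient) * (R0 - r)^(-0.5)
}

# int_{r1}^{r2} J(r) 2 pi r dr, analytic.
# With u = R0 - r: int (R0 - u) u^(-1/2) du = 2 R0 sqrt(u) - (2/3) u^(3/2).
flux_annulus_integral <- function(geom, ambient, r1, r2 = geom$contact_radius) {
  R0 <- geom$contact_radius
  Fu <- function(u) 2 * R0 * sqrt(u) - (2 / 3) * u^1.5
  2 * pi * flux_prefactor(geom, ambient) * (Fu(R0 - r1) - Fu(R0 - r2))
}

#' Share of the total evaporation carried by the edge annulus
#'
#' Fraction of [total_evaporation_rate()] leaving through the annulus
#' `[R0 (1 - delta_r_fraction), R0]`. Purely geometric (independent of
#' droplet size and ambient conditions) for the (R0 - r)^(-1/2) flux.
#'
#' @param delta_r_fraction Annulus width as a fraction of the contact radius
#'   (the calculation-domain width; 0.05 in the kinetic-pathway analysis).
#' @return Dimensionless share in (0, 1).
#' @export
edge_annulus_share <- function(delta_r_fraction) {
  stopifnot(delta_r_fraction > 0, delta_r_fraction < 1)
  f <- delta_r_fraction
  (2 * sqrt(f) - (2 / 3) * f^1.5) / (4 / 3)
}

#' Liquid volume held in the edge annulus
#'
#' Integral of the spherical-cap height profile over the annulus
#' `[R0 (1 - delta_r_fraction), R0]`, evaluated analytically.
#'
#' @inheritParams total_evaporation_rate
#' @inheritParams edge_annulus_share
#' @return Volume in m^3.
#' @export
annulus_liquid_volume <- function(geom, delta_r_fraction = 0.05) {
  stopifnot(inherits(geom, "droplet_geometry"),
            delta_r_fraction > 0, delta_r_fraction < 1)
  a <- geom$contact_radius
  Rs <- cap_sphere_radius(geom)
  ct <- cos(geom$contact_angle)
  # int 2 pi r h(r) dr = -(2 pi/3)(Rs^2 - r^2)^(3/2) - pi r^2 Rs cos(theta)
  Fn <- function(r) -(2 * pi / 3) * (Rs^2 - r^2)^1.5 - pi * r^2 * Rs * ct
  Fn(a) - Fn(a * (1 - delta_r_fraction))
}

#' Water mass evaporated from the edge annulus in one time step
#'
#' The calculation-domain water loss of the kinetic-pathway analysis: the
#' analytic annulus integral of [local_evaporation_flux()] times `delta_t`.
#' Errors when the demanded loss exceeds the water initially present in the
#' annulus (film volume from the cap height profile times `water_density`).
#'
#' @inheritParams total_evaporation_rate
#' @inheritParams edge_annulus_share
#' @param delta_t Time step, s.
#' @param water_density Liquid density used for the availability check,
#'   kg m^-3.
#' @return Evaporated water mass, kg.
#' @export
annulus_water_loss <- function(geom, ambient, delta_r_fraction = 0.05,
                               delta_t = 5, water_density = 998) {
  stopifnot(delta_t >= 0)
  loss <- total_evaporation_rate(geom, ambient) *
    edge_annulus_share(delta_r_fraction) * delta_t
  available <- water_density * annulus_liquid_volume(geom, delta_r_fraction)
  if (loss > available)
    stop(sprintf(paste0(
      "annulus dry-out: %.3g kg demanded but only %.3g kg of liquid in the ",
      "annulus; use a smaller `delta_t`"), loss, available))
  loss
}

#' Pinned-contact-line evaporation of a droplet
#'
#' Forward-integrates the droplet volume under the diffusion-limited rate at
#' fixed contact radius (pinned mode), re-inverting the spherical-cap
#' relation for the contact angle after each step. Integration stops early
#' (with a truncation flag) if the contact angle would fall below
#' `theta_floor` or the volume would go negative.
#'
#' @inheritParams total_evaporation_rate
#' @param delta_t Time step, s.
#' @param n_steps Number of steps (>= 1).
#' @param theta_floor Contact-angle floor in rad (default 5 deg); the pinned
#'   thin-film model is not meaningful below it.
#' @param water_density Density converting mass loss to volume loss, kg m^-3.
#' @return A data.frame of class `evaporation_trace` with columns `time_s`,
#'   `contact_radius_m`, `contact_angle_rad`, `volume_m3`, `water_lost_kg`;
#'   attribute `truncated` flags an early stop.
#' @export
evolve_droplet <- function(geom, ambient, delta_t = 5, n_steps = 60,
                           theta_floor = 5 * pi / 180, water_density = 998) {
  stopifnot(inherits(geom, "droplet_geometry"),
            inherits(ambient, "ambient_conditions"),
            delta_t > 0, n_steps >= 1)
  a <- geom$contact_radius
  th <- geom$contact_angle
  V <- cap_volume(geom)
  V_floor <- pi * a^3 * cap_volume_factor(theta_floor)
  out <- data.frame(time_s = 0, contact_radius_m = a, contact_angle_rad = th,
                    volume_m3 = V, water_lost_kg = 0)
  truncated <- FALSE
  lost <- 0
  for (k in seq_len(n_steps)) {
    g <- droplet_geometry(a, th)
    dm <- total_evaporation_rate(g, ambient) * delta_t
    V_new <- V - dm / water_density
    if (V_new < V_floor) {
      truncated <- TRUE
      break
    }
    if (dm > 0) {
      th <- contact_angle_for_volume(V_new, a,
                                     interval = c(theta_floor / 10, pi / 2))
      V <- V_new
    }
    lost <- lost + dm
    out <- rbind(out, data.frame(time_s = k * delta_t, contact_radius_m = a,
                                 contact_angle_rad = th, volume_m3 = V,
                                 water_lost_kg = lost))
  }
  attr(out, "truncated") <- truncated
  attr(out, "theta_floor") <- theta_floor
  class(out) <- c("evaporation_trace", "data.frame")
  out
}
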