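#' Fluid properties of the droplet solution
#'
#' Bundles density, viscosity and a linear surface-tension model
#' \eqn{\gamma(w_{peg}) = \gamma_{ref} + slope (w_{peg} - w_{ref})}. PEG is
#' surface active, so the slope is negative; the default calibration gives
#' the 64 mN/m surface tension of the droplet solution at 5 wt% PEG and a
#' gentle decrease across the composition range spanned by phase separation.
#'
#' @param density Solution density, kg m^-3.
#' @param viscosity Dynamic viscosity, Pa s.
#' @param gamma_ref Reference surface tension, N/m.
#' @param w_peg_ref PEG mass fraction at which `gamma_ref` applies.
#' @param gamma_slope d(gamma)/d(w_peg), N/m per unit mass fraction
#'   (negative).
#' @param w_peg_range Composition range over which the linear model is
#'   trusted.
#' @return An object of class `fluid_properties`.
#' @export
fluid_properties <- function(density = 1030, viscosity = 3e-3,
                             gamma_ref = 0.064, w_peg_ref = 0.05,
                             gamma_slope = -0.05,
                             w_peg_range = c(0.0, 0.20)) {
  stopifnot(density > 0, viscosity > 0, gamma_ref > 0, gamma_slope < 0)
  fl <- structure(list(density = density, viscosity = viscosity,
                       gamma_ref = gamma_ref, w_peg_ref = w_peg_ref,
                       gamma_slope = gamma_slope, w_peg_range = w_peg_range),
                  class = "fluid_properties")
  if (surface_tension(fl, max(w_peg_range)) <= 0)
    stop("surface-tension model goes non-positive within `w_peg_range`")
  fl
}

#' Surface tension at a given PEG mass fraction
#' @param fluid A [fluid_properties()].
#' @param w_peg PEG mass fraction(s).
#' @return Surface tension, N/m.
#' @export
surface_tension <- function(fluid, w_peg) {
  stopifnot(inherits(fluid, "fluid_properties"))
  fluid$gamma_ref + fluid$gamma_slope * (w_peg - fluid$w_peg_ref)
}

#' Bond number of the sessile droplet
#'
#' \eqn{Bo = \rho g R^2 / \gamma} with R the contact radius. Bo << 1 means
#' surface tension, not gravity, sets the droplet shape.
#'
#' @param fluid A [fluid_properties()].
#' @param geom A [droplet_geometry()].
#' @param g Gravitational acceleration, m s^-2.
#' @return Dimensionless Bond number.
#' @export
bond_number <- function(fluid, geom, g = 9.8) {
  stopifnot(inherits(fluid, "fluid_properties"),
            inherits(geom, "droplet_geometry"))
  fluid$density * g * geom$contact_radius^2 / fluid$gamma_ref
}

# surface-lowering rate -dh/dt(r) > 0 of a pinned evaporating cap,
# via dtheta/dt = (dV/dt)/(dV/dtheta) and the analytic dh/dtheta
cap_lowering_rate <- function(geom, ambient, fluid, r) {
  a <- geom$contact_radius
  th <- geom$contact_angle
  dVdt <- -total_evaporation_rate(geom, ambient) / fluid$density
  eps <- 1e-7
  dVdth <- pi * a^3 *
    (cap_volume_factor(th + eps) - cap_volume_factor(th - eps)) / (2 * eps)
  dthdt <- dVdt / dVdth
  Rs <- a / sin(th)
  dRs <- -a * cos(th) / sin(th)^2
  dhdth <- Rs * dRs / sqrt(pmax(Rs^2 - r^2, 1e-300)) -
    (dRs * cos(th) - Rs * sin(th))
  -dhdth * dthdt
}

#' Depth-averaged capillary (coffee-ring) outflow velocity
#'
#' Height-averaged radial velocity of the evaporation-driven flow in a
#' pinned cap, from mass conservation in the thin film:
#' \deqn{\bar u(r) = \frac{1}{\rho r h(r)} \int_0^r
#'   [\rho \dot h(r') - J(r')]\, r'\,dr',}
#' where \eqn{\dot h > 0} is the local surface-lowering rate and J the local
#' evaporation flux. Edge-enhanced evaporation makes \eqn{\bar u > 0}
#' (outward) — the coffee-ring flow that inward Marangoni stresses must beat.
#'
#' @param geom A [droplet_geometry()].
#' @param ambient An [ambient_conditions()].
#' @param fluid A [fluid_properties()].
#' @param eval_r_fraction Evaluation radius as a fraction of the contact
#'   radius (default 0.95, the inner edge of the calculation domain); values
#'   too close to 1 are rejected because h -> 0 there.
#' @return Velocity in m s^-1 (positive = outward).
#' @export
capillary_velocity_scale <- function(geom, ambient, fluid,
                                     eval_r_fraction = 0.95) {
  stopifnot(eval_r_fraction > 0)
  if (eval_r_fraction >= 0.999)
    stop("`eval_r_fraction` too close to the contact line (h -> 0)")
  a <- geom$contact_radius
  r <- eval_r_fraction * a
  h <- cap_height_profile(geom, r)
  sink_int <- stats::integrate(
    function(rp) fluid$density *
      cap_lowering_rate(geom, ambient, fluid, rp) * rp,
    0, r, rel.tol = 1e-10)$value
  flux_int <- flux_annulus_integral(geom, ambient, 0, r) / (2 * pi)
  (sink_int - flux_int) / (fluid$density * r * h)
}

#' Marangoni velocity scale in the lubrication approximation
#'
#' Surface-tension-gradient-driven film velocity
#' \eqn{u_M = coeff\, \Delta\gamma\, h / (\mu\, L)} with h the film thickness
#' at the evaluation radius and L the length over which the surface-tension
#' difference acts. `coeff = 1/2` is the depth-averaged Couette value.
#'
#' @param delta_gamma Surface-tension difference, N/m.
#' @inheritParams capillary_velocity_scale
#' @param gradient_length Length over which `delta_gamma` acts, m; defaults
#'   to the contact radius.
#' @param coeff O(1) lubrication coefficient.
#' @return Velocity in m s^-1.
#' @export
marangoni_velocity_scale <- function(delta_gamma, geom, fluid,
                                     gradient_length = NULL,
                                     eval_r_fraction = 0.95, coeff = 0.5) {
  stopifnot(delta_gamma >= 0)
  if (is.null(gradient_length)) gradient_length <- geom$contact_radius
  stopifnot(gradient_length > 0)
  h <- cap_height_profile(geom, eval_r_fraction * geom$contact_radius)
  coeff * delta_gamma * h / (fluid$viscosity * gradient_length)
}

#' Surface-tension difference required to reverse the capillary outflow
#'
#' Two balances are offered:
#' \describe{
#'   \item{`"pressure"` (default)}{Marangoni stress against the capillary
#'     (Laplace) pressure of the cap acting across the film:
#'     \eqn{\Delta\gamma = coeff\, h_{edge}\, (2\gamma/R_{sphere})}. This is
#'     the balance that sets the mN/m magnitude needed in practice.}
#'   \item{`"velocity"`}{The \eqn{\Delta\gamma} at which
#'     [marangoni_velocity_scale()] equals [capillary_velocity_scale()]
#'     (exact closed-form inversion of the linear relation).}
#' }
#'
#' @inheritParams marangoni_velocity_scale
#' @param ambient An [ambient_conditions()] (used by the velocity balance).
#' @param balance Which balance to invert.
#' @return Required surface-tension difference, N/m.
#' @export
required_delta_gamma <- function(geom, ambient, fluid,
                                 gradient_length = NULL,
                                 balance = c("pressure", "velocity"),
                                 eval_r_fraction = 0.95, coeff = 0.5) {
  balance <- match.arg(balance)
  if (is.null(gradient_length)) gradient_length <- geom$contact_radius
  h <- cap_height_profile(geom, eval_r_fraction * geom$contact_radius)
  if (balance == "pressure") {
    p_laplace <- 2 * fluid$gamma_ref / cap_sphere_radius(geom)
    return(coeff * h * p_laplace)
  }
  u_cap <- capillary_velocity_scale(geom, ambient, fluid, eval_r_fraction)
  u_cap * fluid$viscosity * gradient_length / (coeff * h)
}

#' Achievable surface-tension difference across a composition jump
#'
#' Evaluates the surface-tension model at two PEG mass fractions — typically
#' the single-phase droplet composition and the PEG-rich endpoint of the
#' first phase split — and returns the magnitude of the difference.
#'
#' @param fluid A [fluid_properties()].
#' @param w_peg_from,w_peg_to PEG mass fractions of the two regions.
#' @return |gamma(from) - gamma(to)| in N/m.
#' @export
achievable_delta_gamma <- function(fluid, w_peg_from, w_peg_to) {
  abs(surface_tension(fluid, w_peg_to) - surface_tension(fluid, w_peg_from))
}

#' Detect the phase-separation front in a radial intensity profile
#'
#' The front radius R2 is located at the maximum magnitude of the radial
#' intensity gradient after moving-average smoothing. Ties are broken
#' towards the outermost maximizer. Profiles with no gradient peak standing
#' out from the baseline (flat, or featureless monotone ramps) return
#' `NA_real_` (no-front signal).
#'
#' @param r Radial positions, m (increasing).
#' @param intensity Intensity samples at `r`.
#' @param window Moving-average window length (odd; samples); the default
#'   spans roughly one front width at the packaged sampling density.
#' @param prominence Required ratio of the peak gradient magnitude to the
#'   median gradient magnitude.
#' @return The front radius R2 in m, or `NA_real_` when no front is found.
#' @export
detect_front <- function(r, intensity, window = 7L, prominence = 2) {
  stopifnot(length(r) == length(intensity), length(r) >= window,
            all(is.finite(intensity)), all(diff(r) > 0))
  window <- as.integer(window)
  if (window %% 2L == 0L) window <- window + 1L
  sm <- as.numeric(stats::filter(intensity, rep(1 / window, window),
                                 sides = 2))
  keep <- which(!is.na(sm))
  rs <- r[keep]
  ss <- sm[keep]
  n <- length(ss)
  if (n < 3L) return(NA_real_)
  # centred gradient at the interior nodes (no half-sample shift)
  grad <- abs((ss[3:n] - ss[1:(n - 2)]) / (rs[3:n] - rs[1:(n - 2)]))
  if (max(grad) <= 0) return(NA_real_)
  if (max(grad) < prominence * stats::median(grad)) return(NA_real_)
  nodes <- rs[2:(n - 1)]
  # outermost maximizer, refined by the centroid of the contiguous
  # half-maximum region around it (sub-sample localization)
  peaks <- which(grad >= max(grad) * (1 - 1e-12))
  pk <- peaks[length(peaks)]
  lo <- pk
  while (lo > 1L && grad[lo - 1L] >= 0.5 * grad[pk]) lo <- lo - 1L
  hi <- pk
  while (hi < length(grad) && grad[hi + 1L] >= 0.5 * grad[pk]) hi <- hi + 1L
  idx <- lo:hi
  sum(grad[idx] * nodes[idx]) / sum(grad[idx])
}

#' Linear fit of the phase-separation-front trajectory
#'
#' Ordinary least squares of `R2(t) = R2_at_0 - v * t`; the front of the
#' phase-separated region moves inward at constant speed, so `L = R - R2`
#' grows linearly in time (advective, not diffusive, kinematics).
#'
#' @param time_s Times, s.
#' @param R2_m Front radii, m (at least 3 finite pairs).
#' @return A list with `v` (front speed, m/s, positive = inward), `se_v`
#'   (its standard error), `R2_at_0` (intercept, m) and `r_squared`.
#' @export
psf_linear_fit <- function(time_s, R2_m) {
  ok <- is.finite(time_s) & is.finite(R2_m)
  if (sum(ok) < 3L) stop("need at least 3 finite (time, R2) records")
  fit <- stats::lm(R2_m[ok] ~ time_s[ok])
  # summary.lm warns on exact synthetic lines ("essentially perfect fit")
  sm <- suppressWarnings(summary(fit))
  cf <- sm$coefficients
  list(v = -cf[2, 1], se_v = cf[2, 2], R2_at_0 = cf[1, 1],
       r_squared = sm$r.squared)
}
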