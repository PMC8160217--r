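#' Spherical-cap droplet geometry
#'
#' A sessile droplet pinned on a flat substrate is described by its contact
#' radius \eqn{a} and contact angle \eqn{\theta}. Volume, apex height and the
#' full height profile follow from spherical-cap geometry. The evaporation
#' flux model used downstream assumes \eqn{\theta < \pi/2}; the constructor
#' admits the hemispherical limit \eqn{\theta = \pi/2} because it is the
#' closed-form anchor of the contact-angle factor.
#'
#' @param contact_radius Contact (footprint) radius in m. Must be positive.
#' @param contact_angle Contact angle in rad, in (0, pi/2].
#' @return An object of class `droplet_geometry`.
#' @examples
#' g <- droplet_geometry(0.9e-3, 45 * pi / 180)
#' cap_volume(g)        # ~0.5 uL in m^3
#' cap_height(g)
#' @export
droplet_geometry <- function(contact_radius, contact_angle) {
  stopifnot(is.numeric(contact_radius), length(contact_radius) == 1L,
            is.numeric(contact_angle), length(contact_angle) == 1L)
  if (!is.finite(contact_radius) || contact_radius <= 0)
    stop("`contact_radius` must be a positive length (m)")
  if (!is.finite(contact_angle) || contact_angle <= 0 ||
      contact_angle > pi / 2 + 1e-12)
    stop("`contact_angle` must lie in (0, pi/2] rad")
  structure(list(contact_radius = contact_radius,
                 contact_angle = min(contact_angle, pi / 2)),
            class = "droplet_geometry")
}

#' @export
print.droplet_geometry <- function(x, ...) {
  cat(sprintf(
    "<droplet_geometry> a = %.4g mm, theta = %.2f deg, V = %.4g uL\n",
    1e3 * x$contact_radius, 180 / pi * x$contact_angle, 1e9 * cap_volume(x)))
  invisible(x)
}

# (2 - 3 cos t + cos^3 t) / (3 sin^3 t): V = pi a^3 * capfac(theta)
cap_volume_factor <- function(theta) {
  (2 - 3 * cos(theta) + cos(theta)^3) / (3 * sin(theta)^3)
}

#' Volume of the spherical cap
#' @param geom A [droplet_geometry()].
#' @return Volume in m^3.
#' @export
cap_volume <- function(geom) {
  stopifnot(inherits(geom, "droplet_geometry"))
  pi * geom$contact_radius^3 * cap_volume_factor(geom$contact_angle)
}

#' Apex height of the spherical cap
#' @inheritParams cap_volume
#' @return Height at the droplet centre, m.
#' @export
cap_height <- function(geom) {
  stopifnot(inherits(geom, "droplet_geometry"))
  geom$contact_radius * (1 - cos(geom$contact_angle)) / sin(geom$contact_angle)
}

# radius of the sphere the cap is cut from
cap_sphere_radius <- function(geom) geom$contact_radius / sin(geom$contact_angle)

#' Height profile h(r) of the spherical cap
#'
#' @inheritParams cap_volume
#' @param r Radial positions in m, `0 <= r <= contact_radius`.
#' @return Local film thickness h(r) in m; `h(contact_radius) = 0`.
#' @export
cap_height_profile <- function(geom, r) {
  stopifnot(inherits(geom, "droplet_geometry"), is.numeric(r))
  a <- geom$contact_radius
  if (any(r < -1e-15 | r > a * (1 + 1e-12)))
    stop("`r` must lie in [0, contact_radius]")
  r <- pmin(pmax(r, 0), a)
  Rs <- cap_sphere_radius(geom)
  pmax(sqrt(pmax(Rs^2 - r^2, 0)) - Rs * cos(geom$contact_angle), 0)
}

#' Construct a droplet from its volume and contact angle
#'
#' Inverts the spherical-cap relation for the contact radius. A 0.5 uL
#' droplet at 45 deg has a contact radius of about 0.90 mm.
#'
#' @param volume Droplet volume in m^3.
#' @param contact_angle Contact angle in rad, in (0, pi/2].
#' @return A [droplet_geometry()].
#' @export
droplet_from_volume <- function(volume, contact_angle) {
  stopifnot(is.numeric(volume), length(volume) == 1L, volume > 0)
  a <- (volume / (pi * cap_volume_factor(contact_angle)))^(1 / 3)
  droplet_geometry(a, contact_angle)
}

#' Contact angle of a pinned cap holding a given volume
#'
#' Inverts V(theta) at fixed contact radius; used when a pinned droplet
#' loses volume by evaporation.
#'
#' @param volume Target volume, m^3.
#' @param contact_radius Fixed contact radius, m.
#' @param interval Search interval for theta, rad.
#' @return Contact angle in rad.
#' @export
contact_angle_for_volume <- function(volume, contact_radius,
                                     interval = c(1e-6, pi / 2)) {
  stopifnot(volume > 0, contact_radius > 0)
  f <- function(th) pi * contact_radius^3 * cap_volume_factor(th) - volume
  if (f(interval[2]) < 0)
    stop("volume exceeds the capacity of the cap within `interval`")
  if (f(interval[1]) > 0)
    stop("volume below the cap volume at the lower bound of `interval`")
  stats::uniroot(f, interval, tol = 1e-14)$root
}

#' Ambient vapour conditions around an evaporating droplet
#'
#' Either `relative_humidity` or `ambient_vapor_concentration` must be given;
#' when both are given they must agree.
#'
#' @param vapor_diffusivity Diffusion coefficient of water vapour in air,
#'   m^2 s^-1 (default 2.5e-5 near room temperature).
#' @param saturated_vapor_concentration Saturated vapour mass concentration
#'   at the droplet surface, kg m^-3 (default 2.3e-2, ~22 C; a package
#'   default, supply measured values where available).
#' @param relative_humidity Ambient relative humidity as a fraction in [0, 1].
#' @param ambient_vapor_concentration Ambient vapour concentration, kg m^-3.
#' @return An object of class `ambient_conditions`.
#' @export
ambient_conditions <- function(vapor_diffusivity = 2.5e-5,
                               saturated_vapor_concentration = 2.3e-2,
                               relative_humidity = NULL,
                               ambient_vapor_concentration = NULL) {
  stopifnot(vapor_diffusivity > 0, saturated_vapor_concentration > 0)
  if (is.null(relative_humidity) && is.null(ambient_vapor_concentration))
    stop("supply `relative_humidity` or `ambient_vapor_concentration`")
  if (is.null(ambient_vapor_concentration))
    ambient_vapor_concentration <-
      relative_humidity * saturated_vapor_concentration
  if (is.null(relative_humidity))
    relative_humidity <-
      ambient_vapor_concentration / saturated_vapor_concentration
  if (abs(ambient_vapor_concentration -
          relative_humidity * saturated_vapor_concentration) >
      1e-12 * saturated_vapor_concentration)
    stop("`relative_humidity` and `ambient_vapor_concentration` disagree")
  if (ambient_vapor_concentration < 0 ||
      ambient_vapor_concentration > saturated_vapor_concentration)
    stop("ambient vapour concentration must lie in [0, n_s]")
  structure(list(vapor_diffusivity = vapor_diffusivity,
                 saturated_vapor_concentration = saturated_vapor_concentration,
                 ambient_vapor_concentration = ambient_vapor_concentration,
                 relative_humidity = relative_humidity),
            class = "ambient_conditions")
}

#' @export
print.ambient_conditions <- function(x, ...) {
  cat(sprintf(
    "<ambient_conditions> D = %.3g m^2/s, n_s = %.3g kg/m^3, RH = %.0f%%\n",
    x$vapor_diffusivity, x$saturated_vapor_concentration,
    100 * x$relative_humidity))
  invisible(x)
}
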