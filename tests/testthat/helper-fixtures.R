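# shared study-condition fixtures: 0.5 uL droplet at 45 deg, room conditions
paper_geom <- function() droplet_from_volume(0.5e-9, 45 * pi / 180)

paper_ambient <- function(rh = 0.6) ambient_conditions(relative_humidity = rh)

paper_fluid <- function() fluid_properties()

paper_binodal <- function() default_synthetic_binodal()

# independent quadrature oracle for the contact-angle factor, using the
# substitution u = tanh(pi * tau) to map (0, Inf) onto (0, 1)
f_theta_oracle <- function(theta) {
  g <- function(u) {
    tau <- atanh(u) / pi
    du <- pi * (1 - u^2)                 # du/dtau
    num <- 1 + cosh(2 * theta * tau)
    den <- sinh(2 * pi * tau)
    val <- ifelse(tau < 1e-10, (pi - theta) / pi,
                  num / den * tanh((pi - theta) * tau))
    val / du
  }
  sin(theta) / (1 + cos(theta)) +
    4 * stats::integrate(g, 0, 1, rel.tol = 1e-10, abs.tol = 0)$value
}

# implicit integrated Michaelis-Menten progress curve:
# K_M log(s0/s) + (s0 - s) = kcat * e * t, root-solved for s(t)
integrated_mm_oracle <- function(t, s0, e, kcat, K_M) {
  vapply(t, function(tt) {
    f <- function(s) K_M * log(s0 / s) + (s0 - s) - kcat * e * tt
    stats::uniroot(f, c(s0 * 1e-12, s0), tol = 1e-15)$root
  }, numeric(1))
}
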