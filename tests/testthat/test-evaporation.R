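test_that("contact-angle factor hits its closed-form anchors", {
  expect_equal(contact_angle_factor(pi / 2), 2, tolerance = 1e-6)
  expect_equal(contact_angle_factor(1e-7), 4 / pi, tolerance = 1e-6)
})

test_that("contact-angle factor agrees with an independent quadrature oracle", {
  for (th in c(pi / 4, 25 * pi / 180, 40 * pi / 180, 80 * pi / 180))
    expect_equal(contact_angle_factor(th), f_theta_oracle(th),
                 tolerance = 1e-6)
})

test_that("contact-angle factor is continuous and strictly increasing", {
  th <- seq(0.01, pi / 2, length.out = 60)
  f <- contact_angle_factor(th)
  expect_true(all(diff(f) > 0))
  expect_true(all(f >= 4 / pi - 1e-9 & f <= 2 + 1e-9))
  expect_error(contact_angle_factor(pi), "0, pi")
})

test_that("total rate is zero without a vapour gradient and linear in R, D, dn", {
  g <- paper_geom()
  expect_equal(total_evaporation_rate(g, paper_ambient(rh = 1)), 0)
  amb <- paper_ambient()
  r1 <- total_evaporation_rate(g, amb)
  g2 <- droplet_geometry(2 * g$contact_radius, g$contact_angle)
  expect_equal(total_evaporation_rate(g2, amb), 2 * r1, tolerance = 1e-12)
  amb2 <- ambient_conditions(vapor_diffusivity = 2 * amb$vapor_diffusivity,
                             relative_humidity = 0.6)
  expect_equal(total_evaporation_rate(g, amb2), 2 * r1, tolerance = 1e-12)
  amb3 <- ambient_conditions(relative_humidity = 0.8)
  expect_equal(total_evaporation_rate(g, amb3), 0.5 * r1, tolerance = 1e-12)
})

test_that("total rate reproduces direct evaluation of the evaporation law", {
  g <- droplet_geometry(0.9e-3, 40 * pi / 180)
  amb <- ambient_conditions(vapor_diffusivity = 2.5e-5,
                            saturated_vapor_concentration = 2.3e-2,
                            relative_humidity = 0.6)
  direct <- pi * 0.9e-3 * 2.5e-5 * (2.3e-2 * 0.4) *
    f_theta_oracle(40 * pi / 180)
  expect_equal(total_evaporation_rate(g, amb), direct, tolerance = 1e-8)
})

test_that("local flux has the inverse-square-root edge divergence", {
  g <- paper_geom()
  amb <- paper_ambient()
  R0 <- g$contact_radius
  r <- seq(0, R0 * 0.999, length.out = 100)
  J <- local_evaporation_flux(r, g, amb)
  expect_true(all(diff(J) > 0))
  # halving the distance to the contact line multiplies J by sqrt(2)
  d <- 0.2 * R0
  expect_equal(local_evaporation_flux(R0 - d / 2, g, amb) /
                 local_evaporation_flux(R0 - d, g, amb),
               sqrt(2), tolerance = 1e-12)
  expect_error(local_evaporation_flux(R0, g, amb), "singular")
})

test_that("disk integral of the local flux reproduces the total rate", {
  set.seed(42)
  for (k in 1:50) {
    g <- droplet_geometry(runif(1, 2e-4, 2e-3), runif(1, 0.1, pi / 2))
    amb <- ambient_conditions(vapor_diffusivity = runif(1, 1e-5, 4e-5),
                              saturated_vapor_concentration = runif(1, 0.01, 0.04),
                              relative_humidity = runif(1, 0, 0.95))
    # substitution u = sqrt(R0 - r) removes the integrable edge singularity
    R0 <- g$contact_radius
    disk <- stats::integrate(
      function(u) 4 * pi * u * (R0 - u^2) *
        local_evaporation_flux(R0 - u^2, g, amb),
      0, sqrt(R0), rel.tol = 1e-12, abs.tol = 0)$value
    expect_equal(disk, total_evaporation_rate(g, amb), tolerance = 1e-8)
  }
})

test_that("annulus loss is additive, quadrature-consistent and bounded", {
  g <- paper_geom()
  amb <- paper_ambient()
  expect_equal(annulus_water_loss(g, amb, delta_t = 0), 0)
  dt <- 5
  loss <- annulus_water_loss(g, amb, 0.05, dt)
  # numerical quadrature oracle over the annulus (u = sqrt(R0 - r))
  R0 <- g$contact_radius
  quad <- stats::integrate(
    function(u) 4 * pi * u * (R0 - u^2) *
      local_evaporation_flux(R0 - u^2, g, amb),
    0, sqrt(0.05 * R0), rel.tol = 1e-12, abs.tol = 0)$value * dt
  expect_equal(loss, quad, tolerance = 1e-8)
  # annulus + inner disk = total
  inner <- total_evaporation_rate(g, amb) * dt *
    (1 - edge_annulus_share(0.05))
  expect_equal(loss + inner, total_evaporation_rate(g, amb) * dt,
               tolerance = 1e-12)
  expect_error(annulus_water_loss(g, amb, 0.05, delta_t = 1e5), "dry-out")
})

test_that("pinned evaporation decreases the contact angle through the 45-25 deg band", {
  g <- paper_geom()
  amb <- paper_ambient()
  tr <- evolve_droplet(g, amb, delta_t = 5, n_steps = 120)
  expect_true(all(diff(tr$contact_angle_rad) < 0))
  expect_true(all(diff(tr$volume_m3) < 0))
  expect_true(all(diff(tr$water_lost_kg) > 0))
  expect_true(all(tr$contact_radius_m == g$contact_radius))
  # the droplet passes 25 deg within a several-minute drying window
  t25 <- tr$time_s[which(tr$contact_angle_rad < 25 * pi / 180)[1]]
  expect_true(is.finite(t25) && t25 > 60 && t25 < 600)
})

test_that("evaporation trace is constant without a vapour gradient", {
  tr <- evolve_droplet(paper_geom(), paper_ambient(rh = 1), n_steps = 5)
  expect_equal(length(unique(tr$contact_angle_rad)), 1L)
  expect_equal(tr$water_lost_kg, rep(0, 6))
})

test_that("evaporation trace converges under time-step refinement", {
  g <- paper_geom()
  amb <- paper_ambient()
  coarse <- evolve_droplet(g, amb, delta_t = 10, n_steps = 12)
  fine <- evolve_droplet(g, amb, delta_t = 1.25, n_steps = 96)
  finer <- evolve_droplet(g, amb, delta_t = 0.625, n_steps = 192)
  v_end <- function(tr) tr$volume_m3[nrow(tr)]
  err_coarse <- abs(v_end(coarse) - v_end(finer))
  err_fine <- abs(v_end(fine) - v_end(finer))
  expect_lt(err_fine, err_coarse)
  # O(delta_t): halving the step from 2.5 to 1.25 shrinks the defect
  expect_lt(err_fine / v_end(finer), 1e-3)
})
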