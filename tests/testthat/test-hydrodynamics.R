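test_that("Bond number follows its exact scaling laws", {
  fl <- paper_fluid()
  g <- paper_geom()
  bo <- bond_number(fl, g)
  fl2 <- fluid_properties(gamma_ref = 2 * fl$gamma_ref)
  expect_equal(bond_number(fl2, g), bo / 2, tolerance = 1e-14)
  g2 <- droplet_geometry(3 * g$contact_radius, g$contact_angle)
  expect_equal(bond_number(fl, g2), 9 * bo, tolerance = 1e-14)
})

test_that("surface-tension dominance: Bo ~ 0.1 for the 0.5 uL droplet", {
  bo <- bond_number(paper_fluid(), paper_geom())
  expect_lt(abs(bo - 0.1), 0.05)
})

test_that("capillary outflow is outward and of the observed flow magnitude", {
  u <- capillary_velocity_scale(paper_geom(), paper_ambient(), paper_fluid())
  expect_gt(u, 0)
  # same order as the ~6 um/s front speed: within [0.1, 100] um/s
  expect_gt(u, 1e-7)
  expect_lt(u, 1e-4)
  expect_error(
    capillary_velocity_scale(paper_geom(), paper_ambient(), paper_fluid(),
                             eval_r_fraction = 0.9999),
    "contact line")
})

test_that("film mass balance closes over the whole contact disk", {
  # integral of (rho hdot - J) r dr over [0, R0) must vanish: everything the
  # surface loses leaves through the evaporative flux
  g <- paper_geom()
  amb <- paper_ambient()
  fl <- paper_fluid()
  sink <- stats::integrate(
    function(r) fl$density *
      evapLLPS:::cap_lowering_rate(g, amb, fl, r) * r,
    0, g$contact_radius, rel.tol = 1e-10)$value
  flux <- evapLLPS:::flux_annulus_integral(g, amb, 0) / (2 * pi)
  expect_equal(sink / flux, 1, tolerance = 1e-6)
})

test_that("Marangoni velocity scale is linear and invertible", {
  g <- paper_geom()
  fl <- paper_fluid()
  expect_equal(marangoni_velocity_scale(0, g, fl), 0)
  u1 <- marangoni_velocity_scale(1e-3, g, fl)
  expect_equal(marangoni_velocity_scale(2e-3, g, fl), 2 * u1,
               tolerance = 1e-14)
  fl2 <- fluid_properties(viscosity = 2 * fl$viscosity)
  expect_equal(marangoni_velocity_scale(1e-3, g, fl2), u1 / 2,
               tolerance = 1e-14)
})

test_that("velocity-balance delta-gamma is the exact inverse of the Marangoni scale", {
  g <- paper_geom()
  amb <- paper_ambient()
  fl <- paper_fluid()
  dg <- required_delta_gamma(g, amb, fl, balance = "velocity")
  expect_equal(marangoni_velocity_scale(dg, g, fl),
               capillary_velocity_scale(g, amb, fl), tolerance = 1e-12)
  fl2 <- fluid_properties(viscosity = 2 * fl$viscosity)
  expect_equal(required_delta_gamma(g, amb, fl2, balance = "velocity"),
               2 * dg, tolerance = 1e-10)
})

test_that("pressure-balance delta-gamma is mN/m-scale and achievable", {
  g <- paper_geom()
  amb <- paper_ambient()
  fl <- paper_fluid()
  dg <- required_delta_gamma(g, amb, fl)
  expect_gt(dg, 0.1e-3)
  expect_lt(dg, 10e-3)
  # the composition jump across the first split provides enough delta-gamma
  bin <- paper_binodal()
  pw <- kinetic_pathway(composition(0.05, 0.10), paper_geom(),
                        paper_ambient(), bin$curve, n_steps = 1)
  tie <- tie_line_through(composition(w_peg = pw$w_peg[2],
                                      w_dex = pw$w_dex[2]),
                          bin$curve, bin$tie_slope)
  ach <- achievable_delta_gamma(fl, pw$w_peg[1], tie$peg_rich$w_peg)
  expect_gt(ach, dg)
})

test_that("front detection locates steps and rejects featureless profiles", {
  r <- seq(0, 1e-3, length.out = 201)
  dr <- r[2] - r[1]
  step <- ifelse(r > 6e-4, 1, 0)
  expect_lte(abs(detect_front(r, step, window = 1) - 6e-4), dr)
  expect_true(is.na(detect_front(r, rep(0.5, 201))))
  expect_true(is.na(detect_front(r, r / 1e-3)))  # monotone ramp, no front
})

test_that("front detection recovers a noisy sigmoid within two sample spacings", {
  prof <- synth_front_profiles(R0 = 9e-4, v = 6e-6, times = c(10, 30, 50),
                               sigma_rel = 0.05, n_r = 200, seed = 3)
  truth <- attr(prof, "truth")
  dr <- 9e-4 / 199
  for (i in seq_along(unique(prof$time_s))) {
    tt <- unique(prof$time_s)[i]
    sub <- prof[prof$time_s == tt, ]
    expect_lt(abs(detect_front(sub$r_m, sub$intensity) - truth$R2[i]),
              2 * dr)
  }
})

test_that("front trajectory fit recovers exact and noisy kinematics", {
  t <- seq(0, 60, by = 5)
  exact <- psf_linear_fit(t, 8e-4 - 6e-6 * t)
  expect_equal(exact$v, 6e-6, tolerance = 1e-12)
  expect_equal(exact$R2_at_0, 8e-4, tolerance = 1e-12)
  expect_equal(exact$r_squared, 1)
  flat <- psf_linear_fit(t, rep(5e-4, length(t)))
  expect_equal(flat$v, 0)
  expect_error(psf_linear_fit(c(1, 2), c(1e-4, 2e-4)), "at least 3")
})

test_that("front-speed estimation is unbiased over repeated noise draws", {
  t <- seq(0, 60, by = 5)
  clean <- 8e-4 - 6e-6 * t
  set.seed(99)
  z <- replicate(200, {
    fit <- psf_linear_fit(t, clean + rnorm(length(t), 0, 2e-5))
    (fit$v - 6e-6) / fit$se_v
  })
  expect_lt(abs(mean(z)), 0.5)
})

test_that("detect_front + psf_linear_fit pipeline recovers generator kinematics", {
  prof <- synth_front_profiles(R0 = 9e-4, v = 6e-6,
                               times = seq(5, 55, by = 5),
                               sigma_rel = 0.05, seed = 21)
  times <- unique(prof$time_s)
  R2 <- vapply(times, function(tt) {
    sub <- prof[prof$time_s == tt, ]
    detect_front(sub$r_m, sub$intensity)
  }, numeric(1))
  fit <- psf_linear_fit(times, R2)
  expect_lt(abs(fit$v - 6e-6), 3 * fit$se_v + 1e-12)
  expect_gt(fit$r_squared, 0.98)
})
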