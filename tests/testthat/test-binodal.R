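test_that("binodal fit recovers exact coefficients from noise-free points", {
  truth <- c(a = 0.3, b = -4.5, c = 1.2, d = -25)
  x <- seq(0.01, 0.35, length.out = 12)
  y <- truth["a"] * exp(truth["b"] * sqrt(x) + truth["c"] * x +
                          truth["d"] * x^3)
  fit <- fit_binodal(data.frame(w_dex = x, w_peg = y))
  expect_equal(unname(fit$coefficients), unname(truth), tolerance = 1e-6)
})

test_that("binodal fit from a noisy synthetic table stays within 2% of truth", {
  tb <- synth_binodal_table(noise_level = 0.01, n_points = 40,
                            n_tie_lines = 0, seed = 7)
  pts <- data.frame(w_dex = tb$w_dex_wt_pct / 100,
                    w_peg = tb$w_peg_wt_pct / 100)
  fit <- fit_binodal(pts)
  curve <- paper_binodal()$curve
  xs <- seq(min(pts$w_dex), max(pts$w_dex), length.out = 100)
  rel <- abs(predict(fit, xs) / predict(curve, xs) - 1)
  expect_lt(max(rel), 0.02)
})

test_that("binodal fit enforces its preconditions", {
  x <- c(0.05, 0.1, 0.2, 0.3)
  expect_error(fit_binodal(data.frame(w_dex = x, w_peg = rev(x))),
               "at least 5")
  expect_error(fit_binodal(data.frame(w_dex = c(x, 0.3),
                                      w_peg = c(rev(x), 0.5))), "distinct")
  # an increasing cloud of points cannot give a decreasing binodal
  xx <- seq(0.05, 0.3, length.out = 8)
  expect_error(fit_binodal(data.frame(w_dex = xx, w_peg = xx)),
               "not strictly decreasing")
})

test_that("two-phase test uses a strict boundary and the validity range", {
  bin <- paper_binodal()$curve
  on_curve <- composition(w_peg = predict(bin, 0.1), w_dex = 0.1)
  expect_false(is_two_phase(on_curve, bin))
  expect_false(is_two_phase(composition(w_peg = 0, w_dex = 0.1), bin))
  just_above <- composition(w_peg = predict(bin, 0.1) * 1.0001, w_dex = 0.1)
  expect_true(is_two_phase(just_above, bin))
  expect_error(is_two_phase(composition(0.05, 0.6), bin), "validity range")
})

test_that("the paper anchor mixtures start single-phase on the packaged binodal", {
  bin <- paper_binodal()$curve
  expect_false(is_two_phase(composition(w_peg = 0.05, w_dex = 0.10), bin))
  expect_false(is_two_phase(composition(w_peg = 0.09, w_dex = 0.04), bin))
})

test_that("tie lines bracket the bulk and land on the curve", {
  bin <- paper_binodal()$curve
  bulk <- composition(w_peg = 0.09, w_dex = 0.14)
  tie <- tie_line_through(bulk, bin)
  # endpoints on the binodal within the type tolerance
  expect_lt(abs(tie$peg_rich$w_peg - predict(bin, tie$peg_rich$w_dex)), 1e-4)
  expect_lt(abs(tie$dex_rich$w_peg - predict(bin, tie$dex_rich$w_dex)), 1e-4)
  expect_true(tie$peg_rich$w_dex < bulk$w_dex &&
                bulk$w_dex < tie$dex_rich$w_dex)
  # independent bisection oracle for the intersections
  slope <- -0.55
  g <- function(x) predict(bin, x) - (bulk$w_peg + slope * (x - bulk$w_dex))
  bisect <- function(lo, hi) {
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (g(lo) * g(mid) <= 0) hi <- mid else lo <- mid
    }
    (lo + hi) / 2
  }
  expect_equal(tie$peg_rich$w_dex, bisect(0.001, bulk$w_dex),
               tolerance = 1e-8)
  expect_equal(tie$dex_rich$w_dex, bisect(bulk$w_dex, 0.5),
               tolerance = 1e-8)
  expect_error(tie_line_through(composition(0.01, 0.02), bin),
               "single-phase")
})

test_that("tie-line length decreases to its tangent-chord limit at the binodal", {
  bin <- paper_binodal()$curve
  eps <- c(0.3, 0.1, 0.03, 0.01, 0.003)
  tll <- vapply(eps, function(e) {
    bulk <- composition(w_peg = predict(bin, 0.14) * (1 + e), w_dex = 0.14)
    tie_line_length(tie_line_through(bulk, bin))
  }, numeric(1))
  expect_true(all(diff(tll) < 0))
  # limiting geometry: as the quench vanishes the dextran-rich endpoint
  # collapses onto the bulk point and the tie line tends to the chord the
  # same slope cuts through the on-curve point towards the PEG-rich branch
  slope <- -0.55
  y0 <- predict(bin, 0.14)
  g <- function(x) predict(bin, x) - (y0 + slope * (x - 0.14))
  x_far <- stats::uniroot(g, c(0.002, 0.139), tol = 1e-12)$root
  chord <- sqrt((x_far - 0.14)^2 + (predict(bin, x_far) - y0)^2)
  expect_equal(tll[length(tll)], chord, tolerance = 0.05)
  # deeper quenches on the same slope family have longer tie lines
  shallow <- tie_line_through(
    composition(w_peg = predict(bin, 0.14) * 1.05, w_dex = 0.14), bin)
  deep <- tie_line_through(
    composition(w_peg = predict(bin, 0.14) * 1.6, w_dex = 0.14), bin)
  expect_gt(tie_line_length(deep), tie_line_length(shallow))
})

test_that("lever rule satisfies mass balance for random splits", {
  bin <- paper_binodal()$curve
  set.seed(11)
  for (k in 1:100) {
    x0 <- runif(1, 0.08, 0.25)
    bulk0 <- composition(w_peg = predict(bin, x0) * runif(1, 1.05, 1.6),
                         w_dex = x0)
    tie <- tie_line_through(bulk0, bin, tie_slope = runif(1, -0.8, -0.4))
    tpos <- runif(1)
    p <- c(tie$peg_rich$w_dex, tie$peg_rich$w_peg) * (1 - tpos) +
      c(tie$dex_rich$w_dex, tie$dex_rich$w_peg) * tpos
    bulk <- composition(w_peg = p[2], w_dex = p[1])
    split <- lever_rule(bulk, tie)
    f <- split$mass_fraction_dex_rich
    expect_equal(f * tie$dex_rich$w_peg + (1 - f) * tie$peg_rich$w_peg,
                 bulk$w_peg, tolerance = 1e-8)
    expect_equal(f * tie$dex_rich$w_dex + (1 - f) * tie$peg_rich$w_dex,
                 bulk$w_dex, tolerance = 1e-8)
    expect_equal(split$ratio_dex_to_peg / (1 + split$ratio_dex_to_peg),
                 f, tolerance = 1e-12)
  }
})

test_that("lever rule handles midpoint, endpoint and off-segment cases", {
  bin <- paper_binodal()$curve
  bulk <- composition(w_peg = 0.09, w_dex = 0.14)
  tie <- tie_line_through(bulk, bin)
  mid <- composition(
    w_peg = (tie$peg_rich$w_peg + tie$dex_rich$w_peg) / 2,
    w_dex = (tie$peg_rich$w_dex + tie$dex_rich$w_dex) / 2)
  s_mid <- lever_rule(mid, tie)
  expect_equal(s_mid$ratio_dex_to_peg, 1, tolerance = 1e-9)
  expect_equal(s_mid$mass_fraction_dex_rich, 0.5, tolerance = 1e-9)
  s_end <- lever_rule(tie$dex_rich, tie)
  expect_equal(s_end$mass_fraction_dex_rich, 1)
  off <- composition(w_peg = bulk$w_peg + 0.02, w_dex = bulk$w_dex)
  expect_error(lever_rule(off, tie), "tie-line segment")
})

test_that("concentrating preserves the polymer ratio exactly", {
  c0 <- composition(w_peg = 0.05, w_dex = 0.10)
  expect_equal(concentrate(c0, 0), c0)
  c1 <- concentrate(c0, 0.2)
  expect_equal(c1$w_peg, 0.0625)
  expect_equal(c1$w_dex, 0.125)
  # ratio invariant across any sequence of concentration steps
  cc <- c0
  for (f in c(0.1, 0.25, 0.3)) cc <- concentrate(cc, f)
  expect_equal(cc$w_peg / cc$w_dex, 0.5, tolerance = 1e-12)
  expect_error(concentrate(c0, 0.9), "dry-out")
})
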