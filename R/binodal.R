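#' Composition of a PEG/dextran aqueous mixture
#'
#' A point in the (w_dex, w_peg) phase plane. Mass fractions are stored as
#' fractions in [0, 1); the water fraction is implied.
#'
#' @param w_peg,w_dex Polymer mass fractions (wt fraction, not percent).
#' @return An object of class `composition` with fields `w_peg`, `w_dex`,
#'   `w_water`.
#' @examples
#' composition(w_peg = 0.05, w_dex = 0.10)
#' @export
composition <- function(w_peg, w_dex) {
  stopifnot(is.numeric(w_peg), length(w_peg) == 1L,
            is.numeric(w_dex), length(w_dex) == 1L)
  if (w_peg < 0 || w_dex < 0 || w_peg + w_dex >= 1)
    stop("need w_peg >= 0, w_dex >= 0 and w_peg + w_dex < 1")
  w_peg <- unname(w_peg)
  w_dex <- unname(w_dex)
  structure(list(w_peg = w_peg, w_dex = w_dex,
                 w_water = 1 - w_peg - w_dex),
            class = "composition")
}

#' @export
print.composition <- function(x, ...) {
  cat(sprintf("<composition> %.3g wt%% PEG, %.3g wt%% dextran\n",
              100 * x$w_peg, 100 * x$w_dex))
  invisible(x)
}

# point in the (x = w_dex, y = w_peg) plane
comp_xy <- function(c) c(c$w_dex, c$w_peg)

#' Binodal coexistence curve of the polymer phase plane
#'
#' Empirical Merchuk-type representation of the binodal,
#' \deqn{w_{peg} = B(w_{dex}) = a\,\exp(b\sqrt{w_{dex}} + c\,w_{dex} +
#'   d\,w_{dex}^3),}
#' strictly decreasing over its validity range. Compositions above the curve
#' are in the two-phase coexistence region.
#'
#' @param a,b,c,d Curve coefficients (mass-fraction units).
#' @param validity_range Range of `w_dex` (fraction) over which the curve is
#'   trusted.
#' @param residuals Optional fit residuals (log scale), kept by
#'   [fit_binodal()].
#' @param coef_table Optional coefficient table (estimates and standard
#'   errors) from the fit.
#' @return An object of class `binodal_model`.
#' @seealso [fit_binodal()], [is_two_phase()], [tie_line_through()]
#' @export
binodal_model <- function(a, b, c = 0, d = 0,
                          validity_range = c(0.001, 0.50),
                          residuals = NULL, coef_table = NULL) {
  stopifnot(a > 0, length(validity_range) == 2L,
            validity_range[1] > 0, diff(validity_range) > 0)
  m <- structure(list(coefficients = c(a = a, b = b, c = c, d = d),
                      validity_range = validity_range,
                      residuals = residuals, coef_table = coef_table),
                 class = "binodal_model")
  check_binodal_monotone(m)
  m
}

check_binodal_monotone <- function(model, n = 400L) {
  xs <- seq(model$validity_range[1], model$validity_range[2], length.out = n)
  ys <- predict(model, xs)
  if (any(!is.finite(ys)) || any(ys < 0))
    stop("binodal curve is not finite and non-negative over its validity range")
  if (any(diff(ys) >= 0))
    stop("binodal curve is not strictly decreasing over its validity range; ",
         "fit rejected")
  invisible(TRUE)
}

#' @export
print.binodal_model <- function(x, ...) {
  k <- x$coefficients
  cat(sprintf(
    "<binodal_model> w_peg = %.4g * exp(%.4g sqrt(w) %+.4g w %+.4g w^3),\n",
    k["a"], k["b"], k["c"], k["d"]))
  cat(sprintf("  valid for w_dex in [%.3g, %.3g]\n",
              x$validity_range[1], x$validity_range[2]))
  invisible(x)
}

#' Evaluate the binodal curve
#' @param object A [binodal_model()].
#' @param w_dex Dextran mass fractions.
#' @param ... Unused.
#' @return Predicted `w_peg` on the curve.
#' @export
predict.binodal_model <- function(object, w_dex, ...) {
  k <- unname(object$coefficients)
  unname(k[1] * exp(k[2] * sqrt(w_dex) + k[3] * w_dex + k[4] * w_dex^3))
}

#' Fit a Merchuk-type binodal to a coexistence table
#'
#' Least-squares fit of \eqn{w_{peg} = a \exp(b\sqrt{w_{dex}} + c w_{dex} +
#' d w_{dex}^3)}. The form is linear in (log a, b, c, d) on the log scale,
#' so the fit is an ordinary linear regression of `log(w_peg)`; coefficient
#' standard errors come from the same regression. The fitted curve must be
#' strictly decreasing over the validity range or the fit is rejected.
#'
#' @param coexistence_table A data.frame with columns `w_dex` and `w_peg`
#'   (mass fractions) of at least 5 points with distinct `w_dex`.
#' @param validity_range Validity range of the returned model; defaults to
#'   the data range.
#' @return A [binodal_model()] with residuals and a coefficient table.
#' @export
fit_binodal <- function(coexistence_table, validity_range = NULL) {
  tb <- as.data.frame(coexistence_table)
  if (!all(c("w_dex", "w_peg") %in% names(tb)))
    stop("`coexistence_table` needs columns `w_dex` and `w_peg`")
  tb <- tb[stats::complete.cases(tb[, c("w_dex", "w_peg")]), ]
  if (nrow(tb) < 5L)
    stop("need at least 5 coexistence points to fit the binodal")
  if (anyDuplicated(tb$w_dex))
    stop("`w_dex` values must be distinct")
  if (any(tb$w_dex <= 0) || any(tb$w_peg <= 0))
    stop("coexistence points must have positive mass fractions")
  fit <- stats::lm(log(w_peg) ~ sqrt(w_dex) + w_dex + I(w_dex^3), data = tb)
  cf <- stats::coef(fit)
  ct <- suppressWarnings(summary(fit))$coefficients
  # delta method for a = exp(intercept)
  ct[1, 1:2] <- c(exp(cf[1]), exp(cf[1]) * ct[1, 2])
  rownames(ct) <- c("a", "b", "c", "d")
  if (is.null(validity_range)) validity_range <- range(tb$w_dex)
  binodal_model(a = exp(cf[[1]]), b = cf[[2]], c = cf[[3]], d = cf[[4]],
                validity_range = validity_range,
                residuals = stats::residuals(fit), coef_table = ct)
}

#' Is a composition in the two-phase region?
#'
#' Strictly above the binodal curve counts as two-phase; points exactly on
#' the curve are single-phase (boundary convention).
#'
#' @param c A [composition()].
#' @param binodal A [binodal_model()].
#' @return `TRUE` if the mixture demixes.
#' @export
is_two_phase <- function(c, binodal) {
  stopifnot(inherits(c, "composition"), inherits(binodal, "binodal_model"))
  rng <- binodal$validity_range
  if (c$w_dex < rng[1] || c$w_dex > rng[2])
    stop(sprintf("w_dex = %.4g outside the binodal validity range [%.3g, %.3g]",
                 c$w_dex, rng[1], rng[2]))
  c$w_peg > predict(binodal, c$w_dex)
}

#' Tie line of the two-phase region
#'
#' @param peg_rich,dex_rich Endpoint [composition()]s on the binodal; the
#'   PEG-rich endpoint must have the larger `w_peg` and the dextran-rich
#'   endpoint the larger `w_dex`.
#' @return An object of class `tie_line`.
#' @export
tie_line <- function(peg_rich, dex_rich) {
  stopifnot(inherits(peg_rich, "composition"), inherits(dex_rich, "composition"))
  if (!(peg_rich$w_peg > dex_rich$w_peg && dex_rich$w_dex > peg_rich$w_dex))
    stop("endpoints do not have the PEG-rich / dextran-rich ordering")
  structure(list(peg_rich = peg_rich, dex_rich = dex_rich), class = "tie_line")
}

#' @export
print.tie_line <- function(x, ...) {
  cat(sprintf(
    "<tie_line> PEG-rich (%.3g, %.3g) -- dex-rich (%.3g, %.3g), TLL = %.3g\n",
    x$peg_rich$w_dex, x$peg_rich$w_peg, x$dex_rich$w_dex, x$dex_rich$w_peg,
    tie_line_length(x)))
  invisible(x)
}

#' Tie line through a two-phase composition
#'
#' Intersects the straight line of slope `tie_slope` (in the (w_dex, w_peg)
#' plane) through `c` with the binodal on either side of `c`, by bisection to
#' a composition tolerance of 1e-8. The bulk composition must be in the
#' two-phase region.
#'
#' @inheritParams is_two_phase
#' @param tie_slope Tie-line slope d(w_peg)/d(w_dex); negative for
#'   segregative PEG/dextran systems.
#' @return A [tie_line()]; both endpoints lie on the binodal.
#' @export
tie_line_through <- function(c, binodal, tie_slope = -0.55) {
  stopifnot(is.numeric(tie_slope), length(tie_slope) == 1L, tie_slope < 0)
  if (!is_two_phase(c, binodal))
    stop("composition is single-phase; no tie line passes through it")
  rng <- binodal$validity_range
  g <- function(x) predict(binodal, x) - (c$w_peg + tie_slope * (x - c$w_dex))
  root <- function(lo, hi, side) {
    if (g(lo) * g(hi) > 0)
      stop(sprintf(paste0(
        "tie line does not intersect the binodal on the %s side within the ",
        "validity range"), side))
    stats::uniroot(g, c(lo, hi), tol = 1e-12)$root
  }
  x1 <- root(rng[1], c$w_dex, "PEG-rich")
  x2 <- root(c$w_dex, rng[2], "dextran-rich")
  tie_line(peg_rich = composition(w_peg = predict(binodal, x1), w_dex = x1),
           dex_rich = composition(w_peg = predict(binodal, x2), w_dex = x2))
}

#' Tie-line length
#'
#' Euclidean distance between the tie-line endpoints in the (w_dex, w_peg)
#' plane; the standard measure of quench depth in ATPS work.
#'
#' @param tie A [tie_line()].
#' @return Length in mass-fraction units.
#' @export
tie_line_length <- function(tie) {
  stopifnot(inherits(tie, "tie_line"))
  sqrt(sum((comp_xy(tie$peg_rich) - comp_xy(tie$dex_rich))^2))
}

#' Lever-rule phase split of a bulk composition
#'
#' Mass balance along a tie line: the mass ratio of the dextran-rich phase to
#' the PEG-rich phase equals the ratio of the distances from the bulk
#' composition to the PEG-rich and dextran-rich endpoints respectively.
#'
#' @inheritParams is_two_phase
#' @param tie A [tie_line()] on which `c` must lie (collinear within 1e-6 of
#'   the tie-line length, between the endpoints).
#' @return An object of class `phase_split` with fields `tie_line`,
#'   `mass_fraction_dex_rich` and `ratio_dex_to_peg`.
#' @export
lever_rule <- function(c, tie) {
  stopifnot(inherits(c, "composition"), inherits(tie, "tie_line"))
  p <- comp_xy(c)
  e1 <- comp_xy(tie$peg_rich)
  e2 <- comp_xy(tie$dex_rich)
  seg <- e2 - e1
  tll <- sqrt(sum(seg^2))
  tpar <- sum((p - e1) * seg) / tll^2
  perp <- sqrt(max(sum((p - e1)^2) - (tpar * tll)^2, 0))
  if (perp > 1e-6 * max(tll, 1e-12) || tpar < -1e-9 || tpar > 1 + 1e-9)
    stop("composition does not lie on the tie-line segment")
  d_peg <- sqrt(sum((p - e1)^2))
  d_dex <- sqrt(sum((p - e2)^2))
  structure(list(tie_line = tie,
                 mass_fraction_dex_rich = d_peg / (d_peg + d_dex),
                 ratio_dex_to_peg = d_peg / d_dex),
            class = "phase_split")
}

#' @export
print.phase_split <- function(x, ...) {
  cat(sprintf(
    "<phase_split> dex-rich : PEG-rich mass ratio = %.3g (dex-rich fraction %.3g)\n",
    x$ratio_dex_to_peg, x$mass_fraction_dex_rich))
  invisible(x)
}

#' Concentrate a composition by removing water
#'
#' Removes a fraction of the total mixture mass as pure water; both polymer
#' fractions scale by `1/(1 - water_loss_fraction)`, so their ratio is
#' preserved exactly.
#'
#' @inheritParams is_two_phase
#' @param water_loss_fraction Fraction of the total mass removed as water;
#'   must be smaller than the available water fraction.
#' @return The concentrated [composition()].
#' @export
concentrate <- function(c, water_loss_fraction) {
  stopifnot(inherits(c, "composition"), is.numeric(water_loss_fraction),
            length(water_loss_fraction) == 1L)
  if (water_loss_fraction < 0)
    stop("`water_loss_fraction` must be non-negative")
  if (water_loss_fraction >= c$w_water)
    stop(sprintf(
      "dry-out: water loss fraction %.3g >= available water fraction %.3g",
      water_loss_fraction, c$w_water))
  composition(w_peg = c$w_peg / (1 - water_loss_fraction),
              w_dex = c$w_dex / (1 - water_loss_fraction))
}
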