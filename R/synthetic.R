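#' @keywords internal
#' run code with a local, seeded RNG state, restoring the caller's stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Default synthetic binodal of a PEG-8000 / dextran-10000-like system
#'
#' The frozen Merchuk curve and constant tie-line slope used throughout the
#' package as the stand-in for a measured PEG/dextran coexistence diagram
#' (synthetic, not a measured data set). Its shape is chosen so that 5/10
#' and 9/4 wt% PEG/dextran mixtures are single-phase and cross the binodal
#' within the first 5-s evaporation step of a 0.5 uL, 45-degree droplet
#' under default room conditions.
#'
#' @return A list with elements `curve` (a [binodal_model()]) and
#'   `tie_slope`.
#' @export
default_synthetic_binodal <- function() {
  list(curve = binodal_model(a = 0.3555, b = -5.22, c = 0, d = -18.3,
                             validity_range = c(0.001, 0.50)),
       tie_slope = -0.55)
}

#' Generate a synthetic coexistence table
#'
#' Samples `n_points` points from a Merchuk-type binodal (optionally with
#' multiplicative Gaussian noise on `w_peg`) plus `n_tie_lines` pairs of
#' noise-free tie-line endpoints at the given constant slope, mimicking a
#' measured ATPS coexistence table. Ground truth is attached as attributes.
#'
#' @param curve A [binodal_model()]; default [default_synthetic_binodal()].
#' @param tie_slope Constant tie-line slope.
#' @param n_points Number of binodal points.
#' @param n_tie_lines Number of tie-line endpoint pairs.
#' @param noise_level Relative (multiplicative Gaussian) noise on the
#'   binodal `w_peg` values.
#' @param seed Integer seed; same seed and arguments give identical output.
#' @return A data.frame with columns `w_dex_wt_pct`, `w_peg_wt_pct`,
#'   `tie_id` (`NA` for binodal points; tie endpoints share an id), and
#'   attributes `truth` (list with the generating coefficients and slope).
#' @export
synth_binodal_table <- function(curve = NULL, tie_slope = -0.55,
                                n_points = 30L, n_tie_lines = 4L,
                                noise_level = 0, seed = 1L) {
  stopifnot(noise_level >= 0, n_points >= 5L)
  if (is.null(curve)) curve <- default_synthetic_binodal()$curve
  stopifnot(inherits(curve, "binodal_model"))
  rng <- curve$validity_range
  with_seed(seed, {
    x <- seq(rng[1], rng[2], length.out = n_points)
    y <- predict(curve, x)
    if (noise_level > 0)
      y <- y * exp(stats::rnorm(n_points, 0, noise_level))
    out <- data.frame(w_dex_wt_pct = 100 * x, w_peg_wt_pct = 100 * y,
                      tie_id = NA_integer_)
    if (n_tie_lines > 0) {
      # quench compositions spread through the two-phase region
      xq <- seq(0.35, 0.65, length.out = n_tie_lines) * diff(rng) + rng[1]
      for (k in seq_len(n_tie_lines)) {
        bulk <- composition(w_peg = 1.35 * predict(curve, xq[k]),
                            w_dex = xq[k])
        tie <- tie_line_through(bulk, curve, tie_slope)
        out <- rbind(out, data.frame(
          w_dex_wt_pct = 100 * c(tie$peg_rich$w_dex, tie$dex_rich$w_dex),
          w_peg_wt_pct = 100 * c(tie$peg_rich$w_peg, tie$dex_rich$w_peg),
          tie_id = k))
      }
    }
    attr(out, "truth") <- list(coefficients = curve$coefficients,
                               validity_range = rng, tie_slope = tie_slope,
                               noise_level = noise_level, seed = seed)
    out
  })
}

#' Generate a noisy droplet-mass time series
#'
#' Droplet mass versus time from the pinned-cap evaporation model plus
#' additive Gaussian noise (standard deviation `sigma_rel` times the initial
#' mass), mimicking microbalance weighing of an evaporating droplet. The
#' ground-truth initial evaporation rate is attached as an attribute.
#'
#' @param geom Initial [droplet_geometry()].
#' @param ambient An [ambient_conditions()].
#' @param sigma_rel Relative noise level.
#' @param n_samples Number of samples.
#' @param delta_t Sampling interval, s.
#' @param water_density Liquid density, kg m^-3.
#' @param seed Integer seed.
#' @return A data.frame with columns `time_s`, `mass_kg`; attribute `truth`
#'   holds the initial rate (kg/s), geometry and noise level.
#' @export
synth_mass_timeseries <- function(geom, ambient, sigma_rel = 0.01,
                                  n_samples = 60L, delta_t = 5,
                                  water_density = 998, seed = 1L) {
  stopifnot(sigma_rel >= 0, n_samples >= 2L)
  trace <- evolve_droplet(geom, ambient, delta_t = delta_t,
                          n_steps = n_samples - 1L,
                          water_density = water_density)
  m0 <- water_density * cap_volume(geom)
  mass <- m0 - trace$water_lost_kg
  with_seed(seed, {
    noisy <- mass + stats::rnorm(length(mass), 0, sigma_rel * m0)
    out <- data.frame(time_s = trace$time_s, mass_kg = noisy)
    attr(out, "truth") <- list(
      initial_rate_kg_s = total_evaporation_rate(geom, ambient),
      initial_mass_kg = m0, sigma_rel = sigma_rel, seed = seed)
    out
  })
}

#' Generate synthetic radial intensity profiles with an advancing front
#'
#' Radial fluorescence profiles of a droplet whose phase-separated rim
#' advances inward at constant speed: a sigmoidal step centred at
#' `R2(t) = R0 - v t` (low inside, high in the phase-separated annulus) with
#' additive Gaussian noise.
#'
#' @param R0 Droplet contact radius, m.
#' @param v Front speed, m/s (>= 0).
#' @param R2_at_0 Front radius at time zero, m (defaults to `0.95 R0`).
#' @param times Sample times, s; all fronts must stay inside (0, R0).
#' @param front_width Sigmoid width, m.
#' @param sigma_rel Additive noise level relative to the unit step height.
#' @param n_r Number of radial samples per profile.
#' @param seed Integer seed.
#' @return A long-format data.frame with columns `time_s`, `r_m`,
#'   `intensity`; attribute `truth` holds `R0`, `v` and the front positions.
#' @export
synth_front_profiles <- function(R0, v = 6e-6, R2_at_0 = NULL,
                                 times = seq(0, 60, by = 5),
                                 front_width = NULL, sigma_rel = 0.05,
                                 n_r = 200L, seed = 1L) {
  stopifnot(R0 > 0, v >= 0, sigma_rel >= 0, n_r >= 20L)
  if (is.null(front_width)) front_width <- R0 / 60
  if (is.null(R2_at_0)) R2_at_0 <- 0.95 * R0
  R2 <- R2_at_0 - v * times
  if (v > 0) {
    inside <- R2 > 2 * front_width & R2 < R0 - 2 * front_width
    if (any(!inside))
      stop("front leaves the observable domain at times: ",
           paste(times[!inside], collapse = ", "))
  }
  r <- seq(0, R0, length.out = n_r)
  with_seed(seed, {
    out <- do.call(rbind, lapply(seq_along(times), function(i) {
      clean <- 1 / (1 + exp(-(r - R2[i]) / front_width))
      data.frame(time_s = times[i], r_m = r,
                 intensity = clean + stats::rnorm(n_r, 0, sigma_rel))
    }))
    attr(out, "truth") <- list(R0 = R0, v = v, R2 = R2,
                               front_width = front_width,
                               sigma_rel = sigma_rel, seed = seed)
    out
  })
}

#' Write a synthetic table as CSV with a JSON metadata sidecar
#'
#' The ground-truth attributes of the generators travel in a
#' `<path>.meta.json` sidecar so recovery tests can run from files.
#'
#' @param x A data.frame from one of the `synth_*` generators.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_synthetic_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  truth <- attr(x, "truth")
  if (!is.null(truth))
    jsonlite::write_json(truth, paste0(path, ".meta.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a coexistence-table CSV
#'
#' Accepts the wt-percent column convention of [synth_binodal_table()]
#' (`w_dex_wt_pct`, `w_peg_wt_pct`, optional `tie_id`) and returns mass
#' fractions ready for [fit_binodal()].
#'
#' @param path CSV path.
#' @return A data.frame with columns `w_dex`, `w_peg`, `tie_id`.
#' @export
read_coexistence_csv <- function(path) {
  tb <- utils::read.csv(path)
  if (!all(c("w_dex_wt_pct", "w_peg_wt_pct") %in% names(tb)))
    stop("expected columns `w_dex_wt_pct` and `w_peg_wt_pct`")
  data.frame(w_dex = tb$w_dex_wt_pct / 100, w_peg = tb$w_peg_wt_pct / 100,
             tie_id = if ("tie_id" %in% names(tb)) tb$tie_id else NA_integer_)
}
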