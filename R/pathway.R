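#' Evaporation-driven kinetic pathway of phase separation
#'
#' Tracks the composition of the droplet-edge calculation domain — an annulus
#' of width `delta_r_fraction * R0` at the pinned contact line — as
#' evaporation removes water. Each step of `delta_t` seconds:
#' \enumerate{
#'   \item evaluates the analytic annulus integral of the edge-divergent
#'     evaporation flux at the current (pinned, shrinking-angle) geometry,
#'   \item converts that water loss to a mass fraction of the liquid
#'     currently in the annulus and concentrates the bulk composition
#'     (polymers never leave the domain),
#'   \item tests the binodal; once in the two-phase region it attaches the
#'     tie line through the composition, the lever-rule phase split and the
#'     tie-line length (TLL).
#' }
#' The whole annulus composition is re-split from scratch every step; the
#' coexisting phases are not tracked individually after a split.
#'
#' @param c0 Initial single-phase [composition()].
#' @param geom Initial [droplet_geometry()].
#' @param ambient An [ambient_conditions()].
#' @param binodal A [binodal_model()].
#' @param tie_slope Tie-line slope passed to [tie_line_through()].
#' @param delta_r_fraction Calculation-domain width as a fraction of the
#'   contact radius (default 0.05).
#' @param delta_t Time step, s (default 5).
#' @param n_steps Number of steps.
#' @param solution_density Density of the polymer solution, kg m^-3, used to
#'   convert the annulus liquid volume to mass.
#' @param on_dryout `"error"` to fail when a step would remove more water
#'   than the annulus holds; `"truncate"` to return the steps computed so
#'   far with attribute `truncated = TRUE`.
#' @return A data.frame of class `kinetic_pathway` with columns `step`,
#'   `time_s`, `w_peg`, `w_dex`, `annulus_mass_kg` (liquid mass remaining in
#'   the calculation domain), `two_phase`, `ratio_dex_to_peg`,
#'   `mass_frac_dex_rich`, `tll` (split columns are `NA` while single-phase),
#'   and attributes `delta_r_fraction`, `delta_t`, `truncated`.
#' @export
kinetic_pathway <- function(c0, geom, ambient, binodal, tie_slope = -0.55,
                            delta_r_fraction = 0.05, delta_t = 5,
                            n_steps = 3, solution_density = 1030,
                            on_dryout = c("error", "truncate")) {
  stopifnot(inherits(c0, "composition"), n_steps >= 1,
            delta_r_fraction > 0, delta_r_fraction < 1, delta_t > 0)
  on_dryout <- match.arg(on_dryout)
  if (is_two_phase(c0, binodal))
    stop("`c0` must be single-phase (below the binodal) at the start")

  row_for <- function(step, time, comp, mass) {
    two <- is_two_phase(comp, binodal)
    ratio <- frac <- tll <- NA_real_
    if (two) {
      # at very deep quench the constant-slope tie line can leave the
      # validity range; record the split as unresolved rather than abort
      tie <- tryCatch(tie_line_through(comp, binodal, tie_slope),
                      error = function(e) NULL)
      if (!is.null(tie)) {
        split <- lever_rule(comp, tie)
        ratio <- split$ratio_dex_to_peg
        frac <- split$mass_fraction_dex_rich
        tll <- tie_line_length(tie)
      }
    }
    data.frame(step = step, time_s = time, w_peg = comp$w_peg,
               w_dex = comp$w_dex, annulus_mass_kg = mass, two_phase = two,
               ratio_dex_to_peg = ratio, mass_frac_dex_rich = frac, tll = tll)
  }

  comp <- c0
  a <- geom$contact_radius
  th <- geom$contact_angle
  # liquid mass currently in the calculation domain
  m_ann <- solution_density * annulus_liquid_volume(geom, delta_r_fraction)
  out <- row_for(0L, 0, c0, m_ann)
  truncated <- FALSE
  for (k in seq_len(n_steps)) {
    g <- droplet_geometry(a, th)
    dm <- total_evaporation_rate(g, ambient) *
      edge_annulus_share(delta_r_fraction) * delta_t
    phi <- dm / m_ann
    if (phi >= comp$w_water) {
      if (on_dryout == "error")
        stop(sprintf(paste0(
          "annulus dry-out at step %d: water-loss fraction %.3g >= available ",
          "water fraction %.3g; use a smaller `delta_t`"),
          k, phi, comp$w_water))
      truncated <- TRUE
      break
    }
    comp <- concentrate(comp, phi)
    if (comp$w_dex > binodal$validity_range[2]) {
      truncated <- TRUE
      break
    }
    m_ann <- m_ann - dm
    # evolve the whole droplet to update the contact angle for the next flux;
    # the evaporated mass is water, so its volume leaves at water density
    V_new <- cap_volume(g) -
      total_evaporation_rate(g, ambient) * delta_t / 998
    th <- tryCatch(
      contact_angle_for_volume(V_new, a, interval = c(1e-3, pi / 2)),
      error = function(e) th)
    out <- rbind(out, row_for(k, k * delta_t, comp, m_ann))
  }
  attr(out, "delta_r_fraction") <- delta_r_fraction
  attr(out, "delta_t") <- delta_t
  attr(out, "tie_slope") <- tie_slope
  attr(out, "truncated") <- truncated
  class(out) <- c("kinetic_pathway", "data.frame")
  out
}

#' Classify the phase-separation pattern regime of a droplet
#'
#' Two morphologies are observed when evaporation drives a PEG/dextran
#' sessile droplet across the binodal: coalescing lobe-shaped dextran-rich
#' domains (regime 1) when the first phase split produces comparable phase
#' masses, and hundreds of dispersed dextran-rich droplets (regime 2) when
#' the dextran-rich phase is a small mass minority.
#'
#' `mode = "lever_ratio"` runs [kinetic_pathway()] and thresholds the
#' dextran-rich to PEG-rich mass ratio of the first split (default 0.5).
#' `mode = "empirical"` applies the observed composition map: below 4 wt%
#' dextran the pattern is dispersed iff PEG exceeds twice the dextran
#' concentration; at or above 4 wt% dextran it is dispersed iff PEG exceeds
#' about 7 wt%.
#'
#' @inheritParams kinetic_pathway
#' @param mode `"lever_ratio"` or `"empirical"`.
#' @param ratio_threshold Regime-1 threshold on the first-split mass ratio
#'   (lever_ratio mode).
#' @param ... Further arguments passed to [kinetic_pathway()] in lever_ratio
#'   mode (e.g. `delta_t`, `n_steps`).
#' @return One of `"regime1"`, `"regime2"`, `"no_llps"` (the last only in
#'   lever_ratio mode when no split occurs within `n_steps`).
#' @export
classify_regime <- function(c0, mode = c("lever_ratio", "empirical"),
                            binodal = NULL, geom = NULL, ambient = NULL,
                            tie_slope = -0.55, ratio_threshold = 0.5,
                            n_steps = 5, ...) {
  stopifnot(inherits(c0, "composition"))
  mode <- match.arg(mode)
  if (mode == "empirical") {
    if (c0$w_dex < 0.04)
      return(if (c0$w_peg > 2 * c0$w_dex) "regime2" else "regime1")
    return(if (c0$w_peg > 0.07) "regime2" else "regime1")
  }
  if (is.null(binodal) || is.null(geom) || is.null(ambient))
    stop("lever_ratio mode needs `binodal`, `geom` and `ambient`")
  pw <- kinetic_pathway(c0, geom, ambient, binodal, tie_slope = tie_slope,
                        n_steps = n_steps, on_dryout = "truncate", ...)
  first <- which(pw$two_phase)[1]
  if (is.na(first)) return("no_llps")
  if (pw$ratio_dex_to_peg[first] >= ratio_threshold) "regime1" else "regime2"
}

#' Write / read a kinetic pathway as CSV
#'
#' @param pathway A `kinetic_pathway` data.frame.
#' @param path File path.
#' @return `write_pathway_csv` returns `path` invisibly; `read_pathway_csv`
#'   returns the data.frame.
#' @export
write_pathway_csv <- function(pathway, path) {
  stopifnot(inherits(pathway, "kinetic_pathway"))
  utils::write.csv(as.data.frame(pathway), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pathway_csv
#' @export
read_pathway_csv <- function(path) {
  utils::read.csv(path)
}
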