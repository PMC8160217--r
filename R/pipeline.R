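#' Default pipeline configuration
#'
#' The paper-default study conditions: a 0.5 uL droplet at 45 degrees under
#' 60% relative humidity at room temperature, the packaged synthetic
#' PEG/dextran binodal, a 9/4 wt% PEG/dextran starting composition, and the
#' default ribozyme reaction-diffusion parameter set.
#'
#' @return A nested list understood by [run_pipeline()].
#' @export
default_pipeline_config <- function() {
  list(
    ambient = list(vapor_diffusivity = 2.5e-5,
                   saturated_vapor_concentration = 2.3e-2,
                   relative_humidity = 0.6),
    droplet = list(volume_uL = 0.5, contact_angle_deg = 45),
    fluid = list(density = 1030, viscosity = 3e-3, gamma_ref = 0.064,
                 w_peg_ref = 0.05, gamma_slope = -0.05),
    binodal = list(source = "synthetic", tie_slope = -0.55),
    pathway = list(c0_wt_pct = c(9, 4), delta_r_fraction = 0.05,
                   delta_t = 5, n_steps = 3, solution_density = 1030),
    evaporation = list(delta_t = 5, n_steps = 60),
    ribozyme = list(D = 1e-10, kcat = 0.017, K_M = 1e-4, e_bulk = 1e-5,
                    s_bulk = 1e-4, R_d = 10e-6, K_E = 50, K_S = 5, K_P = 1,
                    n_nodes = 120, n_save = 150),
    seed = 1
  )
}

known_config_keys <- function() {
  list(top = c("ambient", "droplet", "fluid", "binodal", "pathway",
               "evaporation", "ribozyme", "seed"),
       ambient = c("vapor_diffusivity", "saturated_vapor_concentration",
                   "relative_humidity", "ambient_vapor_concentration"),
       droplet = c("volume_uL", "contact_angle_deg"),
       fluid = c("density", "viscosity", "gamma_ref", "w_peg_ref",
                 "gamma_slope"),
       binodal = c("source", "file", "tie_slope", "a", "b", "c", "d",
                   "validity_range"),
       pathway = c("c0_wt_pct", "delta_r_fraction", "delta_t", "n_steps",
                   "solution_density"),
       evaporation = c("delta_t", "n_steps"),
       ribozyme = c("D", "kcat", "K_M", "e_bulk", "s_bulk", "R_d",
                    "K_E", "K_S", "K_P", "n_nodes", "n_save", "t_end"))
}

#' Validate a pipeline configuration
#'
#' Fills unspecified blocks from [default_pipeline_config()], rejects unknown
#' keys, and checks the positivity of all physical quantities.
#'
#' @param config A nested list (as from [read_pipeline_config()]).
#' @return The completed, validated config.
#' @export
validate_pipeline_config <- function(config) {
  keys <- known_config_keys()
  bad <- setdiff(names(config), keys$top)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "))
  full <- default_pipeline_config()
  for (blk in intersect(names(config), keys$top)) {
    if (blk == "seed") { full$seed <- config$seed; next }
    badk <- setdiff(names(config[[blk]]), keys[[blk]])
    if (length(badk))
      stop(sprintf("unknown keys in config block `%s`: %s", blk,
                   paste(badk, collapse = ", ")))
    full[[blk]][names(config[[blk]])] <- config[[blk]]
  }
  positive <- c(full$ambient$vapor_diffusivity,
                full$ambient$saturated_vapor_concentration,
                full$droplet$volume_uL, full$droplet$contact_angle_deg,
                full$fluid$density, full$fluid$viscosity,
                full$fluid$gamma_ref, full$pathway$delta_t,
                full$pathway$solution_density, full$evaporation$delta_t,
                full$ribozyme$D, full$ribozyme$kcat, full$ribozyme$K_M,
                full$ribozyme$s_bulk, full$ribozyme$R_d)
  if (any(!is.finite(positive) | positive <= 0))
    stop("all physical quantities in the config must be positive and finite")
  if (full$fluid$gamma_slope >= 0)
    stop("`fluid$gamma_slope` must be negative (PEG lowers surface tension)")
  full
}

#' Read a pipeline configuration from JSON
#' @param path Path to a JSON file.
#' @return The validated config list.
#' @export
read_pipeline_config <- function(path) {
  validate_pipeline_config(
    jsonlite::read_json(path, simplifyVector = TRUE))
}

config_hash <- function(config) {
  config$seed <- NULL  # seed reported separately in the manifest
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA,
                       pretty = FALSE)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline
#'
#' Composes the stages — droplet evaporation trace, kinetic pathway of phase
#' separation with regime classification, Marangoni-vs-capillary flow
#' scaling, and the two-scenario ribozyme reaction-diffusion comparison —
#' from a single configuration, writing CSV/JSON outputs and a run manifest.
#' Deterministic for a fixed config and seed.
#'
#' @param config A config list (see [default_pipeline_config()]) or a path
#'   to a JSON config.
#' @param out_dir Output directory (created if needed).
#' @param seed Optional integer overriding `config$seed`.
#' @return The manifest list, invisibly; written to `manifest.json`.
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         out_dir = tempfile("evapllps_run_"), seed = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  config <- validate_pipeline_config(config)
  if (!is.null(seed)) config$seed <- seed
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "evapLLPS",
                   version = as.character(utils::packageVersion("evapLLPS")),
                   seed = config$seed,
                   config_hash = config_hash(config),
                   stages = list(), outputs = character())
  timer <- function(expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- force(expr)
    list(value = val, seconds = proc.time()[["elapsed"]] - t0)
  }
  fail <- function(stage, e)
    stop(sprintf("pipeline stage `%s` failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)

  geom <- droplet_from_volume(config$droplet$volume_uL * 1e-9,
                              config$droplet$contact_angle_deg * pi / 180)
  ambient <- do.call(ambient_conditions, config$ambient)
  fluid <- do.call(fluid_properties, config$fluid)

  # --- evaporation ---------------------------------------------------------
  st <- tryCatch(timer({
    tr <- evolve_droplet(geom, ambient,
                         delta_t = config$evaporation$delta_t,
                         n_steps = config$evaporation$n_steps)
    f <- file.path(out_dir, "evaporation_trace.csv")
    utils::write.csv(as.data.frame(tr), f, row.names = FALSE)
    f
  }), error = function(e) fail("evaporation", e))
  manifest$stages$evaporation <- list(seconds = st$seconds)
  manifest$outputs <- c(manifest$outputs, st$value)

  # --- binodal -------------------------------------------------------------
  binodal_cfg <- config$binodal
  if (identical(binodal_cfg$source, "synthetic")) {
    if (!is.null(binodal_cfg$a)) {
      binodal <- binodal_model(
        binodal_cfg$a, binodal_cfg$b,
        if (is.null(binodal_cfg$c)) 0 else binodal_cfg$c,
        if (is.null(binodal_cfg$d)) 0 else binodal_cfg$d,
        validity_range = if (is.null(binodal_cfg$validity_range))
          c(0.001, 0.50) else binodal_cfg$validity_range)
    } else {
      binodal <- default_synthetic_binodal()$curve
    }
  } else {
    binodal <- fit_binodal(read_coexistence_csv(binodal_cfg$file))
  }
  tie_slope <- if (is.null(binodal_cfg$tie_slope)) -0.55 else
    binodal_cfg$tie_slope

  # --- kinetic pathway + regime -------------------------------------------
  st <- tryCatch(timer({
    c0 <- composition(w_peg = config$pathway$c0_wt_pct[1] / 100,
                      w_dex = config$pathway$c0_wt_pct[2] / 100)
    pw <- kinetic_pathway(
      c0, geom, ambient, binodal, tie_slope = tie_slope,
      delta_r_fraction = config$pathway$delta_r_fraction,
      delta_t = config$pathway$delta_t, n_steps = config$pathway$n_steps,
      solution_density = config$pathway$solution_density,
      on_dryout = "truncate")
    f <- file.path(out_dir, "kinetic_pathway.csv")
    write_pathway_csv(pw, f)
    regimes <- list(
      lever_ratio = classify_regime(
        c0, "lever_ratio", binodal = binodal, geom = geom,
        ambient = ambient, tie_slope = tie_slope,
        delta_r_fraction = config$pathway$delta_r_fraction,
        delta_t = config$pathway$delta_t,
        solution_density = config$pathway$solution_density),
      empirical = classify_regime(c0, "empirical"))
    list(file = f, pathway = pw, regimes = regimes)
  }), error = function(e) fail("pathway", e))
  manifest$stages$pathway <- list(seconds = st$seconds,
                                  regime = st$value$regimes)
  manifest$outputs <- c(manifest$outputs, st$value$file)
  pw <- st$value$pathway

  # --- marangoni scaling ---------------------------------------------------
  st <- tryCatch(timer({
    u_cap <- capillary_velocity_scale(geom, ambient, fluid)
    dg_req <- required_delta_gamma(geom, ambient, fluid)
    first <- which(pw$two_phase)[1]
    dg_ach <- NA_real_
    if (!is.na(first)) {
      tie <- tie_line_through(
        composition(w_peg = pw$w_peg[first], w_dex = pw$w_dex[first]),
        binodal, tie_slope)
      dg_ach <- achievable_delta_gamma(fluid, pw$w_peg[1],
                                       tie$peg_rich$w_peg)
    }
    res <- list(bond_number = bond_number(fluid, geom),
                capillary_velocity_m_s = u_cap,
                required_delta_gamma_N_m = dg_req,
                achievable_delta_gamma_N_m = dg_ach)
    f <- file.path(out_dir, "marangoni.json")
    jsonlite::write_json(res, f, auto_unbox = TRUE, digits = NA)
    list(file = f, res = res)
  }), error = function(e) fail("marangoni", e))
  manifest$stages$marangoni <- c(list(seconds = st$seconds), st$value$res)
  manifest$outputs <- c(manifest$outputs, st$value$file)

  # --- ribozyme reaction-diffusion ----------------------------------------
  st <- tryCatch(timer({
    rz <- config$ribozyme
    params <- rd_parameters(D = rz$D, kcat = rz$kcat, K_M = rz$K_M,
                            e_bulk = rz$e_bulk, s_bulk = rz$s_bulk,
                            R_d = rz$R_d, K_E = rz$K_E, K_S = rz$K_S,
                            K_P = rz$K_P)
    grid <- rd_grid(n_nodes = rz$n_nodes, n_save = rz$n_save,
                    t_end = rz$t_end)
    cmp <- compare_scenarios(params, grid)
    f1 <- file.path(out_dir, "productivity_dextran.csv")
    f2 <- file.path(out_dir, "productivity_water.csv")
    utils::write.csv(as.data.frame(cmp$dextran), f1, row.names = FALSE)
    utils::write.csv(as.data.frame(cmp$water), f2, row.names = FALSE)
    f3 <- file.path(out_dir, "ribozyme_comparison.json")
    jsonlite::write_json(
      list(time_to_plateau_ratio = cmp$time_to_plateau_ratio,
           plateau_ratio = cmp$plateau_ratio),
      f3, auto_unbox = TRUE, digits = NA)
    list(files = c(f1, f2, f3),
         ratios = list(time_to_plateau_ratio = cmp$time_to_plateau_ratio,
                       plateau_ratio = cmp$plateau_ratio))
  }), error = function(e) fail("ribozyme", e))
  manifest$stages$ribozyme <- c(list(seconds = st$seconds), st$value$ratios)
  manifest$outputs <- c(manifest$outputs, st$value$files)

  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
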