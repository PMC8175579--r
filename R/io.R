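#' Read and write package data files
#'
#' Plain-CSV readers/writers for casts, nutrient profiles, tows, trichome and
#' PAR profiles, diffusivity profiles and flux tables. Files written by the
#' package carry `#`-prefixed provenance header lines and can be read back
#' losslessly.
#'
#' @param profiles,path,x objects to write / file paths.
#' @name nitrobudget-io
NULL

prov_header <- function(seed = NA) {
  c(sprintf("# nitrobudget %s",
            as.character(utils::packageVersion("nitrobudget"))),
    sprintf("# seed: %s", seed),
    sprintf("# written: %s", format(Sys.time(), tz = "UTC")))
}

write_csv_prov <- function(df, path, seed = NA) {
  writeLines(prov_header(seed), path)
  suppressWarnings(utils::write.table(df, path, sep = ",", row.names = FALSE,
                                      append = TRUE, quote = FALSE))
  invisible(path)
}

#' @rdname nitrobudget-io
#' @param seed seed recorded in the provenance header.
#' @export
write_casts_csv <- function(profiles, path, seed = NA) {
  df <- do.call(rbind, lapply(profiles, function(p)
    data.frame(cast_id = attr(p, "cast_id"), time = attr(p, "time"),
               depth_m = p$depth, sigma_theta_kg_m3 = p$sigma)))
  write_csv_prov(df, path, seed)
}

#' @rdname nitrobudget-io
#' @export
read_casts_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  lapply(split(df, df$cast_id), function(d)
    density_profile(d$depth_m, d$sigma_theta_kg_m3, cast_id = d$cast_id[1],
                    time = d$time[1], strict = FALSE))
}

#' @rdname nitrobudget-io
#' @export
write_nutrients_csv <- function(profiles, path, seed = NA) {
  df <- do.call(rbind, lapply(profiles, function(p)
    data.frame(cast_id = attr(p, "cast_id"), species = attr(p, "species"),
               depth_m = p$depth, conc_umol_m3 = p$conc)))
  write_csv_prov(df, path, seed)
}

#' @rdname nitrobudget-io
#' @export
read_nutrients_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  lapply(split(df, interaction(df$cast_id, df$species, drop = TRUE)),
         function(d) nutrient_profile(d$species[1], d$depth_m,
                                      d$conc_umol_m3, cast_id = d$cast_id[1]))
}

#' @rdname nitrobudget-io
#' @export
write_kz_csv <- function(x, path, seed = NA) {
  write_csv_prov(data.frame(
    depth_m = (x$depth_top + x$depth_bottom) / 2,
    kz_m2_s = x$kz_geomean, n_casts = x$n_casts), path, seed)
}

#' @rdname nitrobudget-io
#' @export
write_tows_csv <- function(day, night, path, seed = NA) {
  df <- rbind(cbind(tow_id = attr(day, "tow_id"), phase = "day", day),
              cbind(tow_id = attr(night, "tow_id"), phase = "night", night))
  write_csv_prov(df, path, seed)
}

#' @rdname nitrobudget-io
#' @export
read_tows_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  mk <- function(ph) {
    d <- df[df$phase == ph, ]
    size_fraction_tow(d$tow_id[1], ph, d$carbon_biomass,
                      d$mean_individual_carbon, d$size_class)
  }
  list(day = mk("day"), night = mk("night"))
}

#' Default full-pipeline run configuration
#'
#' Nested list of every input and coefficient of [run_pipeline()]: the
#' synthetic-ocean configuration, Thorpe-method constants, euphotic-zone
#' boundaries, the control-volume polygon, photo-fixation and excretion
#' coefficients, measured export fluxes and isotope endmembers. Any element
#' can be overridden via a YAML file or list passed to [run_config()].
#'
#' @param seed master seed.
#' @return A nested configuration list.
#' @export
default_run_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    sim = list(),
    mixing = list(),
    boundaries = list(uez_base = 60, lez_base = 110, gradient_window = 20),
    control_volume = list(
      polygon = list(c(-89.5, 24.2), c(-86.5, 24.2), c(-86.5, 26.5),
                     c(-89.5, 26.5)),
      depth_extent = 55),
    photofixation = list(fmax = 2e-4, alpha = 2e-6, photoperiod = 12),
    excretion = list(a0 = -2.89, a1 = 0.76, a2 = 0.051,
                     depth_temperature = 11, hours_at_depth = 12),
    exports = list(export_uez = 980, export_lez = 462),
    isotopes = list(delta_nitrate = 3.0, delta_fixation = -1.0,
                    delta_export = 2.9),
    nitrification = list(specific_rate_range = c(0.02, 0.5)),
    out_dir = NULL,
    log_level = "info")
}

#' Load and validate a pipeline configuration
#'
#' @param x `NULL` (defaults), a YAML file path, or a list of overrides;
#'   unknown top-level keys are rejected.
#' @param seed master seed (used when `x` does not set one).
#' @return A validated configuration list.
#' @export
run_config <- function(x = NULL, seed = 1L) {
  cfg <- default_run_config(seed)
  if (is.character(x)) {
    if (!file.exists(x)) stop("config file not found: ", x)
    x <- yaml::read_yaml(x)
  }
  if (!is.null(x)) {
    bad <- setdiff(names(x), names(cfg))
    if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
    for (nm in names(x)) {
      cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(x[[nm]]))
        utils::modifyList(cfg[[nm]], x[[nm]]) else x[[nm]]
    }
  }
  cfg
}

#' Run the full nitrogen-budget pipeline
#'
#' Executes the stages in dependency order on synthetic inputs generated from
#' the configuration: Thorpe-scale diffusivity from the casts; diffusive
#' nitrate fluxes across the upper- and lower-euphotic-zone boundaries;
#' lateral PON transport into the control volume (with eddy detection and
#' attribution at the first time step); UEZ-integrated N2-fixation; migrant
#' active transport; and the assembled budget against the measured exports.
#'
#' @param cfg a configuration from [run_config()] (or a YAML path / override
#'   list, which is passed through [run_config()]).
#' @return A list with per-stage artifacts: `kz`, `flux_uez`, `flux_lez`,
#'   `lateral` (series, stats, eddies, eddy_attribution), `fixation_profile`,
#'   `fixation_uez`, `migrant`, `active_transport`, `nitrification_range`,
#'   `budget`, and the generated fixtures under `inputs`. Written as CSV
#'   artifacts if `cfg$out_dir` is set.
#' @export
run_pipeline <- function(cfg = run_config()) {
  if (!is.list(cfg) || is.null(cfg$boundaries)) cfg <- run_config(cfg)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  sim <- stage("simulate",
               do.call(sim_config, c(cfg$sim, list(seed = cfg$seed))))
  casts <- stage("simulate", gen_density_profiles(sim))
  nuts <- stage("simulate", gen_nutrient_profiles(sim))
  surf <- stage("simulate", gen_surface_fields(sim))
  tri <- stage("simulate", gen_trichome_and_par(sim))
  tow <- stage("simulate", gen_tow_pair(sim))

  mix <- stage("hydrography", do.call(mixing_params, cfg$mixing))
  bins <- seq(0, sim$depth_max, by = 2)
  kz <- stage("hydrography", thorpe_kz(casts, bins, mix))

  b <- cfg$boundaries
  flux_uez <- stage("vertical_flux",
                    boundary_nitrate_flux(nuts$nitrate, kz, b$uez_base,
                                          b$gradient_window))
  flux_lez <- stage("vertical_flux",
                    boundary_nitrate_flux(nuts$nitrate, kz, b$lez_base,
                                          b$gradient_window))

  cvp <- do.call(rbind, cfg$control_volume$polygon)
  cv <- control_volume(cvp, cfg$control_volume$depth_extent)
  lateral <- stage("lateral_transport", {
    pon <- poc_to_pon(bin_tracer(surf$poc, 8))
    series <- control_volume_flux_series(pon, surf$vel, cv)
    eddies <- detect_eddies(surf$ssh, surf$vel)
    attribution <- eddy_flux_attribution(attr(series, "details")[[1]], eddies)
    list(series = series, stats = flux_statistics(series),
         eddies = eddies, eddy_attribution = attribution)
  })

  pf <- stage("local_n_sources", do.call(photofixation_params,
                                         cfg$photofixation))
  fix_prof <- stage("local_n_sources",
                    fixation_rate_profile(tri$trichomes, tri$par, pf))
  fix_uez <- stage("local_n_sources",
                   integrate_fixation(fix_prof, 0, b$uez_base))
  nit_range <- stage("local_n_sources",
                     nitrification_potential(
                       sim$ammonium_mean,
                       cfg$nitrification$specific_rate_range))

  ex <- stage("active_transport", do.call(excretion_params, cfg$excretion))
  migrant <- stage("active_transport", migrant_biomass(tow$day, tow$night))
  active <- stage("active_transport",
                  migrant_excretion(migrant, ex, tow$day$mean_individual_carbon))

  iso <- do.call(isotope_endmembers, cfg$isotopes)
  budget <- stage("nitrogen_budget", assemble_budget(
    export_uez = cfg$exports$export_uez,
    export_lez = cfg$exports$export_lez,
    vertical_flux_uez = flux_uez$flux,
    vertical_flux_lez = flux_lez$flux,
    n2_fixation = fix_uez,
    active_transport = active,
    isotopes = iso))

  out <- list(config = cfg, kz = kz, flux_uez = flux_uez,
              flux_lez = flux_lez, lateral = lateral,
              fixation_profile = fix_prof, fixation_uez = fix_uez,
              migrant = migrant, active_transport = active,
              nitrification_range = nit_range, budget = budget,
              inputs = list(sim = sim, casts = casts, nutrients = nuts,
                            surface = surf, trichomes = tri, tows = tow))
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    wp <- function(df, nm) write_csv_prov(df, file.path(cfg$out_dir, nm),
                                          cfg$seed)
    write_kz_csv(kz, file.path(cfg$out_dir, "kz.csv"), cfg$seed)
    wp(rbind(flux_uez, flux_lez), "vertical_flux.csv")
    wp(as.data.frame(lateral$series), "lateral_flux.csv")
    wp(budget$table, "budget.csv")
  }
  out
}
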