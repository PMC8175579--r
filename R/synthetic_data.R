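#' Configuration of the synthetic-ocean generator
#'
#' Bundles every parameter of the seeded generators that emulate the cruise
#' and satellite inputs: stably stratified CTD casts with injected density
#' overturns, nutrient profiles with a deep nitracline, geostrophically
#' balanced eddying surface fields with a coastal particulate gradient,
#' trichome/PAR profiles and paired day/night zooplankton tows. All
#' generators are pure functions of this configuration (per-generator seeds
#' are split from the master seed by fixed offsets), so repeated calls are
#' bit-identical.
#'
#' @param seed master integer seed.
#' @param n_casts number of CTD casts (default 20).
#' @param depth_max,depth_spacing cast depth span and sample spacing, m.
#' @param n2_background background buoyancy frequency squared, s\eqn{^{-2}}.
#' @param sigma_surface surface potential density anomaly, kg m\eqn{^{-3}}.
#' @param noise_sd density sensor noise SD, kg m\eqn{^{-3}} (kept well below
#'   the overturn-detection noise threshold).
#' @param overturns `"random"` (each cast gets 1-2 overturns at random depths)
#'   or a list (one element per cast) of lists with `depth`, `height` (m) and
#'   optional `completeness` in the unit interval.
#' @param overturn_depth_range,overturn_height_range ranges for random
#'   overturn placement, m.
#' @param n_nutrient_profiles number of nutrient casts.
#' @param nutrient_spacing nutrient sample spacing, m.
#' @param nitracline_depth depth (m) where nitrate reaches 0.1 mmol
#'   m\eqn{^{-3}} (the nitracline onset; 80-125 m in deep oligotrophic
#'   basins).
#' @param nitracline_width logistic width of the nitracline, m.
#' @param surface_nitrate surface nitrate, \eqn{\mu}mol m\eqn{^{-3}} (< 50).
#' @param deep_nitrate_150m nitrate near 150 m, \eqn{\mu}mol m\eqn{^{-3}}
#'   (2500-12000).
#' @param ammonium_mean mean ammonium, \eqn{\mu}mol m\eqn{^{-3}}.
#' @param nitrate_noise_sd,ammonium_noise_sd nutrient noise SDs,
#'   \eqn{\mu}mol m\eqn{^{-3}}.
#' @param lon_range,lat_range surface-field domain, deg.
#' @param cell_deg tracer grid spacing, deg (0.08 deg is roughly the 8-km
#'   analysis resolution).
#' @param vel_cell_deg velocity grid spacing, deg (defaults to `cell_deg`;
#'   set coarser, e.g. 1/3 deg, to emulate a coarse current product).
#' @param n_times,time_step number and spacing (d) of tracer composites.
#' @param vel_time_step velocity product time spacing, d.
#' @param eddies list of Gaussian SSH anomalies: `lon`, `lat`, `radius_km`,
#'   `amplitude` (m; positive = anticyclonic).
#' @param eddy_drift_deg_day westward eddy drift rate, deg/d.
#' @param poc_background offshore background POC, mmol m\eqn{^{-3}}.
#' @param poc_coastal additional POC at the (northern) coast, mmol
#'   m\eqn{^{-3}}.
#' @param coastal_gradient e-folding scale of the coastal POC gradient, km.
#' @param eddy_poc_anomaly POC anomaly trapped in eddy cores, mmol
#'   m\eqn{^{-3}} (applied opposite to the SSH sign: anticyclones trap
#'   oligotrophic water).
#' @param poc_noise_sd relative (lognormal) POC noise SD.
#' @param cloud_fraction fraction of tracer cells masked per composite.
#' @param trichome_max surface trichome abundance, trichomes L\eqn{^{-1}}
#'   (<= 19).
#' @param trichome_decay e-folding depth of trichome abundance, m.
#' @param chl_per_trichome ng chl a per trichome.
#' @param par_surface surface PAR, \eqn{\mu}mol photons m\eqn{^{-2}}
#'   s\eqn{^{-1}}.
#' @param par_k diffuse attenuation coefficient, m\eqn{^{-1}}.
#' @param tow_day_biomass day-tow carbon per size class, mg C m\eqn{^{-2}}.
#' @param tow_indiv_carbon mean individual carbon per class, mg C.
#' @param migrant_fraction migrant carbon as a fraction of day biomass per
#'   class, in the unit interval.
#' @param tow_noise_sd relative (lognormal) noise on day-tow biomass.
#' @param g,rho0 physical constants shared with [mixing_params()].
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_casts = 20L,
                       depth_max = 200, depth_spacing = 0.25,
                       n2_background = 2e-5, sigma_surface = 23,
                       noise_sd = 1e-4,
                       overturns = "random",
                       overturn_depth_range = c(60, 140),
                       overturn_height_range = c(1, 2),
                       n_nutrient_profiles = 8L, nutrient_spacing = 5,
                       nitracline_depth = 117, nitracline_width = 6,
                       surface_nitrate = 30, deep_nitrate_150m = 8000,
                       ammonium_mean = 60,
                       nitrate_noise_sd = 0.5, ammonium_noise_sd = 5,
                       lon_range = c(-92, -85), lat_range = c(23, 28),
                       cell_deg = 0.08, vel_cell_deg = cell_deg,
                       n_times = 10L, time_step = 8, vel_time_step = 4,
                       eddies = list(
                         list(lon = -88.5, lat = 25.5, radius_km = 80,
                              amplitude = 0.15),
                         list(lon = -86.8, lat = 24.2, radius_km = 60,
                              amplitude = -0.10)),
                       eddy_drift_deg_day = 0.02,
                       poc_background = 2, poc_coastal = 8,
                       coastal_gradient = 150, eddy_poc_anomaly = 0.5,
                       poc_noise_sd = 0.05, cloud_fraction = 0.03,
                       trichome_max = 8, trichome_decay = 12,
                       chl_per_trichome = 9,
                       par_surface = 1500, par_k = 0.04,
                       tow_day_biomass = c(120, 180, 150, 80, 30),
                       tow_indiv_carbon = c(0.002, 0.01, 0.05, 0.3, 2),
                       migrant_fraction = c(0.1, 0.15, 0.2, 0.3, 0.4),
                       tow_noise_sd = 0.1,
                       g = 9.81, rho0 = 1025) {
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  pos <- c("n_casts", "depth_max", "depth_spacing", "n2_background",
           "noise_sd", "nitracline_depth", "nitracline_width",
           "surface_nitrate", "deep_nitrate_150m", "ammonium_mean",
           "cell_deg", "time_step", "trichome_max", "trichome_decay",
           "chl_per_trichome", "par_surface", "par_k", "g", "rho0")
  if (!all(vapply(cfg[pos], function(x) all(x > 0), logical(1))))
    stop("all physical parameters must be positive")
  if (cfg$trichome_max > 19)
    warning("trichome_max above the observed 0-19 trichomes/L range")
  if (any(cfg$migrant_fraction < 0 | cfg$migrant_fraction > 1))
    stop("migrant fractions must lie in the unit interval")
  structure(cfg, class = "sim_config")
}

# fixed per-generator seed offsets (documented counter scheme)
.seed_offsets <- c(density = 101L, nutrients = 211L, surface = 307L,
                   trichome = 401L, tows = 503L)

with_gen_seed <- function(cfg, which, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cfg$seed + .seed_offsets[[which]])
  expr
}

#' Generate CTD density profiles with known injected overturns
#'
#' A stably stratified background (constant background N\eqn{^2}) with each
#' specified segment replaced by its density-reversed copy (scaled by the
#' completeness fraction) plus Gaussian sensor noise well below the
#' overturn-rejection threshold. Ground-truth patch boundaries are recorded.
#'
#' @param cfg a [sim_config()].
#' @return A list of [density_profile()] objects with attribute `"truth"`:
#'   one data frame per cast with `start_depth`, `end_depth`, `height`,
#'   `completeness` and the background `N` (1/s).
#' @export
gen_density_profiles <- function(cfg) with_gen_seed(cfg, "density", {
  z <- seq(cfg$depth_spacing, cfg$depth_max, by = cfg$depth_spacing)
  dsig_dz <- cfg$rho0 * cfg$n2_background / cfg$g
  n_true <- sqrt(cfg$n2_background)
  truth <- list()
  profs <- lapply(seq_len(cfg$n_casts), function(k) {
    sig <- cfg$sigma_surface + dsig_dz * z
    if (identical(cfg$overturns, "random")) {
      kk <- sample(1:2, 1)
      spec <- lapply(seq_len(kk), function(q) list(
        depth = stats::runif(1, cfg$overturn_depth_range[1],
                             cfg$overturn_depth_range[2]),
        height = stats::runif(1, cfg$overturn_height_range[1],
                              cfg$overturn_height_range[2]),
        completeness = 1))
    } else spec <- cfg$overturns[[k]]
    tr <- list()
    for (ov in spec) {
      comp <- ov$completeness %||% 1
      if (ov$depth - ov$height / 2 < min(z) ||
          ov$depth + ov$height / 2 > max(z))
        stop("injected overturn outside the profile depth span")
      idx <- which(z >= ov$depth - ov$height / 2 &
                     z <= ov$depth + ov$height / 2)
      sig[idx] <- comp * rev(sig[idx]) + (1 - comp) * sig[idx]
      tr[[length(tr) + 1L]] <- data.frame(
        start_depth = z[idx[1]], end_depth = z[idx[length(idx)]],
        height = ov$height, completeness = comp, N = n_true)
    }
    truth[[k]] <<- do.call(rbind, tr)
    sig <- sig + stats::rnorm(length(z), 0, cfg$noise_sd)
    density_profile(z, sig, cast_id = sprintf("cast%02d", k))
  })
  attr(profs, "truth") <- truth
  profs
})

#' Generate nitrate and ammonium profiles
#'
#' Nitrate is near the surface value through the euphotic zone and rises
#' through a logistic nitracline whose midpoint is placed so the
#' concentration reaches 0.1 mmol m\eqn{^{-3}} at the configured nitracline
#' depth; ammonium is depth-uniform with noise. The analytic gradient is
#' available from [nitrate_gradient_true()].
#'
#' @param cfg a [sim_config()].
#' @return A list with elements `nitrate` and `ammonium`, each a list of
#'   [nutrient_profile()] objects.
#' @export
gen_nutrient_profiles <- function(cfg) with_gen_seed(cfg, "nutrients", {
  z <- seq(0, cfg$depth_max, by = cfg$nutrient_spacing)
  no3 <- nitrate_true(cfg, z)
  lapply2 <- function(f) lapply(seq_len(cfg$n_nutrient_profiles), f)
  list(
    nitrate = lapply2(function(k) nutrient_profile(
      "nitrate", z,
      pmax(0, no3 + stats::rnorm(length(z), 0, cfg$nitrate_noise_sd)),
      cast_id = sprintf("nut%02d", k))),
    ammonium = lapply2(function(k) nutrient_profile(
      "ammonium", z,
      pmax(0, cfg$ammonium_mean +
             stats::rnorm(length(z), 0, cfg$ammonium_noise_sd)),
      cast_id = sprintf("nut%02d", k))))
})

nitracline_midpoint <- function(cfg) {
  amp <- 2 * (cfg$deep_nitrate_150m - cfg$surface_nitrate)
  p_onset <- (100 - cfg$surface_nitrate) / amp
  cfg$nitracline_depth - cfg$nitracline_width * stats::qlogis(p_onset)
}

#' @rdname gen_nutrient_profiles
#' @param z depths, m.
#' @return `nitrate_true` and `nitrate_gradient_true`: the noise-free
#'   nitrate profile (\eqn{\mu}mol m\eqn{^{-3}}) and its exact derivative
#'   (\eqn{\mu}mol m\eqn{^{-4}}) at depths `z`.
#' @export
nitrate_true <- function(cfg, z) {
  zm <- nitracline_midpoint(cfg)
  amp <- 2 * (cfg$deep_nitrate_150m - cfg$surface_nitrate)
  cfg$surface_nitrate + amp * stats::plogis((z - zm) / cfg$nitracline_width)
}

#' @rdname gen_nutrient_profiles
#' @export
nitrate_gradient_true <- function(cfg, z) {
  zm <- nitracline_midpoint(cfg)
  amp <- 2 * (cfg$deep_nitrate_150m - cfg$surface_nitrate)
  p <- stats::plogis((z - zm) / cfg$nitracline_width)
  amp * p * (1 - p) / cfg$nitracline_width
}

#' Generate SSH, geostrophic velocity and POC surface fields
#'
#' SSH is a sum of slowly drifting Gaussian anomalies; velocities are in
#' geostrophic balance with SSH on an f-plane (f at the domain-centre
#' latitude), computed by the same central differences whose flux-form
#' divergence the lateral-transport operator measures, so the generated flow
#' is discretely non-divergent in the interior. POC combines an offshore
#' background, an exponential coastal (northern-boundary) gradient,
#' eddy-trapped anomalies, lognormal noise and a random cloud mask.
#'
#' @param cfg a [sim_config()].
#' @return A list with `ssh` ([ssh_grid()]), `vel` ([velocity_grid()]) and
#'   `poc` ([tracer_grid()], mmol m\eqn{^{-3}}).
#' @export
gen_surface_fields <- function(cfg) with_gen_seed(cfg, "surface", {
  lonv <- seq(cfg$lon_range[1], cfg$lon_range[2], by = cfg$vel_cell_deg)
  latv <- seq(cfg$lat_range[1], cfg$lat_range[2], by = cfg$vel_cell_deg)
  lont <- seq(cfg$lon_range[1], cfg$lon_range[2], by = cfg$cell_deg)
  latt <- seq(cfg$lat_range[1], cfg$lat_range[2], by = cfg$cell_deg)
  t_tr <- seq(0, by = cfg$time_step, length.out = cfg$n_times)
  t_vl <- seq(-cfg$vel_time_step, max(t_tr) + cfg$vel_time_step,
              by = cfg$vel_time_step)
  f <- 2 * 7.2921e-5 * sin(mean(cfg$lat_range) * DEG)

  eta_at <- function(lon, lat, t) {
    eta <- matrix(0, length(lon), length(lat))
    for (e in cfg$eddies) {
      clon <- e$lon - cfg$eddy_drift_deg_day * t
      dx <- outer((lon - clon) * 111.195 * cos(e$lat * DEG), rep(1, length(lat)))
      dy <- outer(rep(1, length(lon)), (lat - e$lat) * 111.195)
      eta <- eta + e$amplitude * exp(-(dx^2 + dy^2) / (2 * e$radius_km^2))
    }
    eta
  }
  geostrophic <- function(eta, lon, lat) {
    nlon <- length(lon); nlat <- length(lat)
    dlam <- mean(diff(lon)) * DEG
    dphi <- mean(diff(lat)) * DEG
    ddx <- function(m) {  # d/di with one-sided edges
      out <- m
      out[2:(nlon - 1), ] <- (m[3:nlon, ] - m[1:(nlon - 2), ]) / 2
      out[1, ] <- m[2, ] - m[1, ]
      out[nlon, ] <- m[nlon, ] - m[nlon - 1, ]
      out
    }
    ddy <- function(m) {
      out <- m
      out[, 2:(nlat - 1)] <- (m[, 3:nlat] - m[, 1:(nlat - 2)]) / 2
      out[, 1] <- m[, 2] - m[, 1]
      out[, nlat] <- m[, nlat] - m[, nlat - 1]
      out
    }
    cosl <- matrix(cos(lat * DEG), length(lon), length(lat), byrow = TRUE)
    u <- -(cfg$g / f) * ddy(eta) / (R_EARTH * dphi)
    v <- (cfg$g / f) * ddx(eta) / (R_EARTH * dlam * cosl)
    list(u = u, v = v)
  }

  eta_v <- array(NA_real_, c(length(lonv), length(latv), length(t_vl)))
  u_v <- eta_v; v_v <- eta_v
  for (it in seq_along(t_vl)) {
    eta <- eta_at(lonv, latv, t_vl[it])
    uv <- geostrophic(eta, lonv, latv)
    eta_v[, , it] <- eta; u_v[, , it] <- uv$u; v_v[, , it] <- uv$v
  }

  poc <- array(NA_real_, c(length(lont), length(latt), length(t_tr)))
  dist_km <- (max(cfg$lat_range) - latt) * 111.195
  coastal <- cfg$poc_coastal * exp(-dist_km / cfg$coastal_gradient)
  for (it in seq_along(t_tr)) {
    base <- cfg$poc_background +
      matrix(coastal, length(lont), length(latt), byrow = TRUE)
    for (e in cfg$eddies) {
      clon <- e$lon - cfg$eddy_drift_deg_day * t_tr[it]
      dx <- outer((lont - clon) * 111.195 * cos(e$lat * DEG),
                  rep(1, length(latt)))
      dy <- outer(rep(1, length(lont)), (latt - e$lat) * 111.195)
      base <- base - sign(e$amplitude) * cfg$eddy_poc_anomaly *
        exp(-(dx^2 + dy^2) / (2 * e$radius_km^2))
    }
    noise <- if (cfg$poc_noise_sd > 0)
      exp(stats::rnorm(length(base), 0, cfg$poc_noise_sd)) else 1
    field <- pmax(0, base * noise)
    if (cfg$cloud_fraction > 0)
      field[stats::runif(length(field)) < cfg$cloud_fraction] <- NA
    poc[, , it] <- field
  }
  list(ssh = ssh_grid(lonv, latv, t_vl, eta_v),
       vel = velocity_grid(lonv, latv, t_vl, u_v, v_v),
       poc = tracer_grid(lont, latt, t_tr, poc, species = "POC",
                         units = "mmol_m3"))
})

#' Generate trichome abundance/chlorophyll and PAR profiles
#'
#' Abundance decays exponentially from `trichome_max` at the surface; PAR
#' follows Beer-Lambert attenuation. Both are deterministic given the
#' configuration.
#'
#' @param cfg a [sim_config()].
#' @return A list with `trichomes` (data frame `depth`, `abundance`,
#'   `chl_per_trichome`) and `par` (data frame `depth`, `irradiance`).
#' @export
gen_trichome_and_par <- function(cfg) {
  zt <- seq(0, 60, by = 2)
  zp <- seq(0, 120, by = 2)
  list(trichomes = data.frame(
         depth = zt,
         abundance = cfg$trichome_max * exp(-zt / cfg$trichome_decay),
         chl_per_trichome = cfg$chl_per_trichome),
       par = data.frame(depth = zp,
                        irradiance = cfg$par_surface * exp(-cfg$par_k * zp)))
}

#' Generate a paired day/night zooplankton tow with known migrant carbon
#'
#' Day biomass is the configured per-class vector with lognormal noise; the
#' night tow adds the known migrant carbon (`migrant_fraction` of the day
#' biomass).
#'
#' @param cfg a [sim_config()].
#' @return A list with `day`, `night` ([size_fraction_tow()] objects) and
#'   `migrant_true` (mg C m\eqn{^{-2}} per class).
#' @export
gen_tow_pair <- function(cfg) with_gen_seed(cfg, "tows", {
  day <- cfg$tow_day_biomass *
    exp(stats::rnorm(5, 0, cfg$tow_noise_sd))
  migrant <- cfg$migrant_fraction * day
  list(day = size_fraction_tow("tow1", "day", day, cfg$tow_indiv_carbon),
       night = size_fraction_tow("tow1", "night", day + migrant,
                                 cfg$tow_indiv_carbon),
       migrant_true = stats::setNames(migrant, zoop_size_classes))
})
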