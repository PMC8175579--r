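R_EARTH <- 6371000  # m
DEG <- pi / 180

#' Convert particulate organic carbon to nitrogen by Redfield stoichiometry
#'
#' Applies the canonical marine organic-matter C:N molar ratio of 106:16
#' elementwise, preserving the mask.
#'
#' @param g a POC [tracer_grid()].
#' @return A PON `tracer_grid` in the same units.
#' @export
poc_to_pon <- function(g) {
  if (!inherits(g, "tracer_grid") || g$species != "POC")
    stop("poc_to_pon expects a POC tracer grid")
  g$tracer <- g$tracer * (16 / 106)
  g$species <- "PON"
  g
}

#' Block-average a tracer grid to a coarser resolution
#'
#' Ocean-colour composites are noisy at native resolution; block means over
#' square-ish blocks (default target 8 km) reduce noise before flux
#' computation. The block mean ignores masked cells; blocks with no valid
#' source cells stay masked.
#'
#' @param g a [tracer_grid()].
#' @param cell_km target cell size, km (default 8).
#' @return A `tracer_grid` on the coarser grid (unchanged if the source is
#'   already at or coarser than the target).
#' @export
bin_tracer <- function(g, cell_km = 8) {
  km_lat <- mean(diff(g$lat)) * 111.195
  km_lon <- mean(diff(g$lon)) * 111.195 * cos(mean(g$lat) * DEG)
  f_lat <- max(1L, round(cell_km / km_lat))
  f_lon <- max(1L, round(cell_km / km_lon))
  if (f_lat == 1L && f_lon == 1L) return(g)
  gi <- ceiling(seq_along(g$lon) / f_lon)
  gj <- ceiling(seq_along(g$lat) / f_lat)
  lon <- as.numeric(tapply(g$lon, gi, mean))
  lat <- as.numeric(tapply(g$lat, gj, mean))
  nt <- length(g$time)
  out <- array(NA_real_, dim = c(length(lon), length(lat), nt))
  for (it in seq_len(nt)) {
    sl <- grid_slice(g, "tracer", it)
    for (bi in seq_along(lon)) for (bj in seq_along(lat)) {
      blk <- sl[gi == bi, gj == bj]
      if (any(is.finite(blk))) out[bi, bj, it] <- mean(blk, na.rm = TRUE)
    }
  }
  tracer_grid(lon, lat, g$time, out, species = g$species, units = g$units)
}

#' Interpolate a velocity grid onto a tracer grid geometry at one time
#'
#' Bilinear interpolation in lon/lat at the two velocity times bracketing
#' `t`, followed by linear interpolation in time (the standard scheme for
#' mapping coarse current products onto an ocean-colour grid).
#'
#' @param v a [velocity_grid()].
#' @param target a grid object supplying the target `lon`/`lat` axes.
#' @param t time (same units as `v$time`); must lie within the velocity span.
#' @return A `velocity_field`: list with `lon`, `lat`, `time`, and matrices
#'   `u`, `v` (`nlon x nlat`); target cells outside the velocity domain are
#'   `NA`.
#' @export
regrid_velocity <- function(v, target, t) {
  if (t < min(v$time) - 1e-9 || t > max(v$time) + 1e-9)
    stop("t outside the velocity time span")
  i0 <- max(which(v$time <= t + 1e-9))
  i1 <- min(which(v$time >= t - 1e-9))
  w <- if (i1 == i0) 0 else (t - v$time[i0]) / (v$time[i1] - v$time[i0])
  pts <- expand.grid(lon = target$lon, lat = target$lat)
  ok <- pts$lon >= min(v$lon) & pts$lon <= max(v$lon) &
    pts$lat >= min(v$lat) & pts$lat <= max(v$lat)
  interp_one <- function(var, it) {
    z <- rep(NA_real_, nrow(pts))
    sl <- grid_slice(v, var, it)
    z[ok] <- pracma::interp2(v$lon, v$lat, t(sl), pts$lon[ok], pts$lat[ok])
    matrix(z, nrow = length(target$lon))
  }
  u <- (1 - w) * interp_one("u", i0) + w * interp_one("u", i1)
  vv <- (1 - w) * interp_one("v", i0) + w * interp_one("v", i1)
  structure(list(lon = target$lon, lat = target$lat, time = t, u = u, v = vv),
            class = "velocity_field")
}

#' Define a polygonal control volume
#'
#' @param polygon two-column matrix or data frame of ordered `lon`, `lat`
#'   vertices (deg); closed automatically if the last vertex differs from the
#'   first. Must have at least 3 distinct vertices.
#' @param depth_extent vertical extent H of the volume, m (default 55); the
#'   surface tracer is assumed vertically uniform over this extent.
#' @return A `control_volume` object with the closed vertex matrix, `H` and an
#'   approximate `surface_area` (m2, equirectangular shoelace at the mean
#'   latitude; the flux computation uses the exact cell-sum area instead).
#' @export
control_volume <- function(polygon, depth_extent = 55) {
  poly <- as.matrix(polygon)
  if (ncol(poly) != 2L) stop("polygon must have two columns (lon, lat)")
  if (any(poly[1, ] != poly[nrow(poly), ])) poly <- rbind(poly, poly[1, ])
  if (nrow(poly) < 4L) stop("polygon needs at least 3 distinct vertices")
  if (depth_extent <= 0) stop("depth_extent must be positive")
  x <- poly[, 1] * DEG * R_EARTH * cos(mean(poly[, 2]) * DEG)
  y <- poly[, 2] * DEG * R_EARTH
  n <- nrow(poly) - 1L
  area <- abs(sum(x[1:n] * y[2:(n + 1)] - x[2:(n + 1)] * y[1:n])) / 2
  structure(list(polygon = poly, H = depth_extent, surface_area = area),
            class = "control_volume")
}

#' Read a control-volume polygon from a plain-text file
#'
#' One `lon lat` pair per line; `#` comments allowed.
#' @param path file path.
#' @param depth_extent see [control_volume()].
#' @return A `control_volume`.
#' @export
read_control_volume <- function(path, depth_extent = 55) {
  m <- as.matrix(utils::read.table(path, comment.char = "#",
                                   col.names = c("lon", "lat")))
  control_volume(m, depth_extent)
}

cell_inside <- function(lon, lat, poly) {
  pts <- expand.grid(lon = lon, lat = lat)
  ins <- sp::point.in.polygon(pts$lon, pts$lat, poly[, 1], poly[, 2]) > 0
  matrix(ins, nrow = length(lon))
}

#' Net lateral tracer flux into a control volume at one time
#'
#' The control volume is rasterised to the tracer grid (cell centres inside
#' the polygon); boundary faces are the grid-cell faces separating inside
#' from outside cells. For each face the inward flux is
#' \eqn{-(u,v)\cdot\hat n \; C_{face} \, L \, H}, with the face concentration
#' the arithmetic mean of the two adjacent cells (falling back to the
#' unmasked one; a face with both neighbours masked contributes zero and is
#' counted in the coverage diagnostic). Face lengths and cell areas use
#' spherical geometry (Earth radius 6371 km); through zonal (N/S) faces the
#' normal transport averages \eqn{v\cos\varphi} of the adjacent cell centres,
#' the flux-form discretisation under which centrally-differenced geostrophic
#' velocities are exactly non-divergent.
#'
#' @param pon a [tracer_grid()] (any species; PON for the nitrogen budget).
#' @param vel a `velocity_field` from [regrid_velocity()] (or a
#'   [velocity_grid()] colocated with `pon` in space, sliced at `time_index`).
#' @param cv a [control_volume()].
#' @param time_index index into `pon$time` (default 1).
#' @param upwind if `TRUE`, use the upwind cell concentration at each face
#'   instead of the centred mean.
#' @return A `lateral_flux` object: `net_flux_per_area` (\eqn{\mu}mol N
#'   m\eqn{^{-2}} d\eqn{^{-1}}, positive into the volume), `area_m2`,
#'   `gross_in`, `gross_out` (\eqn{\mu}mol s\eqn{^{-1}}), `edges` (per-face
#'   table with fluxes in \eqn{\mu}mol s\eqn{^{-1}}) and `n_uncovered`.
#' @export
control_volume_flux <- function(pon, vel, cv, time_index = 1L,
                                upwind = FALSE) {
  nlon <- length(pon$lon); nlat <- length(pon$lat)
  C <- grid_slice(pon, "tracer", time_index)
  if (pon$units == "mmol_m3") C <- C * 1e3  # -> umol m-3
  if (inherits(vel, "velocity_grid")) {
    if (length(vel$lon) != nlon || length(vel$lat) != nlat ||
        max(abs(vel$lon - pon$lon)) > 1e-9 ||
        max(abs(vel$lat - pon$lat)) > 1e-9)
      stop("velocity_grid not colocated with the tracer grid; regrid first")
    it <- which.min(abs(vel$time - pon$time[time_index]))
    U <- grid_slice(vel, "u", it); V <- grid_slice(vel, "v", it)
  } else {
    U <- vel$u; V <- vel$v
  }
  inside <- cell_inside(pon$lon, pon$lat, cv$polygon)
  if (!any(inside)) stop("control volume contains no grid-cell centres")
  dlam <- mean(diff(pon$lon)) * DEG
  dphi <- mean(diff(pon$lat)) * DEG
  cosl <- cos(pon$lat * DEG)
  H <- cv$H
  area <- sum(R_EARTH^2 * dlam * dphi *
                rep(cosl, each = nlon)[as.vector(inside)])

  ins <- function(i, j) i >= 1 && i <= nlon && j >= 1 && j <= nlat &&
    inside[i, j]
  val <- function(M, i, j) if (i >= 1 && i <= nlon && j >= 1 && j <= nlat)
    M[i, j] else NA_real_
  face_conc <- function(ci, co, un) {
    # ci: inside-cell conc, co: outside-neighbour conc, un: normal velocity
    if (upwind) {
      up <- if (is.na(un) || un >= 0) ci else co
      if (is.na(up)) up <- if (is.na(ci)) co else ci
      return(up)
    }
    if (is.na(ci) && is.na(co)) return(NA_real_)
    mean(c(ci, co), na.rm = TRUE)
  }

  rows <- list()
  n_uncov <- 0L
  idx <- which(inside, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]
    faces <- list(
      E = list(ni = i + 1L, nj = j, sgn = -1),
      W = list(ni = i - 1L, nj = j, sgn = +1),
      N = list(ni = i, nj = j + 1L, sgn = -1),
      S = list(ni = i, nj = j - 1L, sgn = +1))
    for (fn in names(faces)) {
      f <- faces[[fn]]
      if (ins(f$ni, f$nj)) next  # interior face
      zonal <- fn %in% c("E", "W")
      if (zonal) {
        un <- mean(c(U[i, j], val(U, f$ni, f$nj)), na.rm = TRUE)
        transport <- un * R_EARTH * dphi  # m2/s
      } else {
        vc_in <- V[i, j] * cosl[j]
        vc_out <- val(V, f$ni, f$nj) *
          if (f$nj >= 1 && f$nj <= nlat) cosl[f$nj] else NA_real_
        un <- mean(c(vc_in, vc_out), na.rm = TRUE)
        transport <- un * R_EARTH * dlam  # m2/s (v cos(phi) * R dlam)
      }
      cf <- face_conc(C[i, j], val(C, f$ni, f$nj), -f$sgn * un)
      if (is.na(cf) || is.na(un)) {
        n_uncov <- n_uncov + 1L
        next
      }
      flux <- f$sgn * transport * cf * H  # umol/s, positive into the volume
      rows[[length(rows) + 1L]] <-
        data.frame(i = i, j = j, lon = pon$lon[i], lat = pon$lat[j],
                   face = fn, flux_umol_s = flux)
    }
  }
  edges <- if (length(rows)) do.call(rbind, rows) else
    stop("all boundary faces masked: no flux can be computed")
  net <- sum(edges$flux_umol_s)
  structure(list(
    net_flux_per_area = net * 86400 / area,
    area_m2 = area,
    gross_in = sum(edges$flux_umol_s[edges$flux_umol_s > 0]),
    gross_out = -sum(edges$flux_umol_s[edges$flux_umol_s < 0]),
    edges = edges, n_uncovered = n_uncov, time = pon$time[time_index]),
    class = "lateral_flux")
}

#' Lateral flux time series over all tracer times
#'
#' Computes [control_volume_flux()] for every time in the tracer grid,
#' interpolating the velocity product to each time with [regrid_velocity()].
#'
#' @param pon a [tracer_grid()].
#' @param vel a [velocity_grid()].
#' @param cv a [control_volume()].
#' @param upwind see [control_volume_flux()].
#' @return A `lateral_flux_series`: data frame `time`, `net_flux_per_area`
#'   with the per-time `lateral_flux` objects attached as attribute
#'   `"details"`.
#' @export
control_volume_flux_series <- function(pon, vel, cv, upwind = FALSE) {
  details <- lapply(seq_along(pon$time), function(it) {
    vf <- regrid_velocity(vel, pon, pon$time[it])
    control_volume_flux(pon, vf, cv, time_index = it, upwind = upwind)
  })
  out <- data.frame(
    time = pon$time,
    net_flux_per_area = vapply(details, `[[`, numeric(1), "net_flux_per_area"))
  structure(out, details = details,
            class = c("lateral_flux_series", "data.frame"))
}

#' Median and interquartile range of a lateral flux series
#'
#' Percentiles by linear interpolation of order statistics
#' (`stats::quantile`, type 7).
#'
#' @param series a `lateral_flux_series` (or numeric vector of fluxes).
#' @return A list with `median`, `q25`, `q75`, `n`.
#' @export
flux_statistics <- function(series) {
  x <- if (is.data.frame(series)) series$net_flux_per_area else as.numeric(series)
  if (!length(x)) stop("empty flux series")
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  list(median = q[2], q25 = q[1], q75 = q[3], n = length(x))
}

#' Detect mesoscale eddies from closed SSH contours
#'
#' For every local SSH extremum, the candidate boundaries are the closed SSH
#' contours (levels spaced `levels_spacing` apart) that enclose that extremum
#' and no other; among them the eddy boundary is the contour with the largest
#' mean along-contour surface speed (velocities interpolated bilinearly onto
#' the contour vertices). Polarity follows the extremum sign (SSH maximum =
#' anticyclonic in the northern hemisphere).
#'
#' @param ssh an [ssh_grid()].
#' @param vel a [velocity_grid()] colocated with `ssh`.
#' @param levels_spacing contour level spacing, m (default 0.02).
#' @param time_index index into `ssh$time` (default 1).
#' @param min_points minimum number of boundary vertices (default 4).
#' @return A list of eddies, each a list with `center_lon`, `center_lat`,
#'   `boundary` (closed two-column matrix), `mean_speed` (m/s),
#'   `mean_radius_m` and `polarity`; empty list if no closed contours.
#' @export
detect_eddies <- function(ssh, vel, levels_spacing = 0.02, time_index = 1L,
                          min_points = 4L) {
  eta <- grid_slice(ssh, "eta", time_index)
  nlon <- length(ssh$lon); nlat <- length(ssh$lat)
  if (diff(range(eta, na.rm = TRUE)) < levels_spacing) return(list())
  # local extrema over a 3x3 neighbourhood, interior cells only
  ext <- list()
  for (i in 2:(nlon - 1)) for (j in 2:(nlat - 1)) {
    nb <- eta[(i - 1):(i + 1), (j - 1):(j + 1)]
    if (any(!is.finite(nb))) next
    ctr <- eta[i, j]
    nb[2, 2] <- NA
    if (ctr > max(nb, na.rm = TRUE))
      ext[[length(ext) + 1L]] <- list(i = i, j = j, sign = 1)
    else if (ctr < min(nb, na.rm = TRUE))
      ext[[length(ext) + 1L]] <- list(i = i, j = j, sign = -1)
  }
  if (!length(ext)) return(list())
  exlon <- vapply(ext, function(e) ssh$lon[e$i], numeric(1))
  exlat <- vapply(ext, function(e) ssh$lat[e$j], numeric(1))
  rng <- range(eta, na.rm = TRUE)
  levels <- seq(rng[1] + levels_spacing / 2, rng[2], by = levels_spacing)
  cl <- grDevices::contourLines(ssh$lon, ssh$lat, eta, levels = levels)
  it <- which.min(abs(vel$time - ssh$time[time_index]))
  U <- grid_slice(vel, "u", it); V <- grid_slice(vel, "v", it)
  eddies <- list()
  for (k in seq_along(ext)) {
    e <- ext[[k]]
    best <- NULL
    for (cc in cl) {
      n <- length(cc$x)
      if (n < min_points) next
      closed <- abs(cc$x[1] - cc$x[n]) < 1e-9 && abs(cc$y[1] - cc$y[n]) < 1e-9
      if (!closed) next
      if (sp::point.in.polygon(ssh$lon[e$i], ssh$lat[e$j], cc$x, cc$y) == 0)
        next
      others <- sp::point.in.polygon(exlon[-k], exlat[-k], cc$x, cc$y)
      if (length(others) && any(others > 0)) next
      ui <- pracma::interp2(ssh$lon, ssh$lat, t(U), cc$x, cc$y)
      vi <- pracma::interp2(ssh$lon, ssh$lat, t(V), cc$x, cc$y)
      spd <- mean(sqrt(ui^2 + vi^2), na.rm = TRUE)
      if (is.null(best) || spd > best$mean_speed)
        best <- list(boundary = cbind(lon = cc$x, lat = cc$y),
                     mean_speed = spd)
    }
    if (!is.null(best)) {
      dx <- (best$boundary[, 1] - ssh$lon[e$i]) * R_EARTH * DEG *
        cos(ssh$lat[e$j] * DEG)
      dy <- (best$boundary[, 2] - ssh$lat[e$j]) * R_EARTH * DEG
      eddies[[length(eddies) + 1L]] <- list(
        center_lon = ssh$lon[e$i], center_lat = ssh$lat[e$j],
        boundary = best$boundary, mean_speed = best$mean_speed,
        mean_radius_m = mean(sqrt(dx^2 + dy^2)),
        polarity = if (e$sign > 0) "anticyclonic" else "cyclonic")
    }
  }
  eddies
}

#' Eddy-associated share of the net lateral flux
#'
#' Recomputes the net control-volume flux using only the boundary faces whose
#' inside-cell centres fall within any detected eddy boundary.
#'
#' @param flux a `lateral_flux` from [control_volume_flux()].
#' @param eddies a list of eddies from [detect_eddies()].
#' @return A list with `eddy_flux_per_area` (\eqn{\mu}mol N m\eqn{^{-2}}
#'   d\eqn{^{-1}}) and `fraction` of the total net flux (NA when the net flux
#'   is zero); both zero flux and zero fraction if no eddies.
#' @export
eddy_flux_attribution <- function(flux, eddies) {
  if (!length(eddies))
    return(list(eddy_flux_per_area = 0, fraction = 0))
  ed <- flux$edges
  in_eddy <- rep(FALSE, nrow(ed))
  for (e in eddies)
    in_eddy <- in_eddy | sp::point.in.polygon(ed$lon, ed$lat,
                                              e$boundary[, 1],
                                              e$boundary[, 2]) > 0
  eddy_net <- sum(ed$flux_umol_s[in_eddy]) * 86400 / flux$area_m2
  net <- flux$net_flux_per_area
  list(eddy_flux_per_area = eddy_net,
       fraction = if (abs(net) > 0) eddy_net / net else NA_real_)
}
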