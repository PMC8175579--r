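#' Gridded surface fields
#'
#' Regular lon/lat/time grids used by the lateral-transport module. Data are
#' stored as arrays with dimensions `(lon, lat, time)`; axes are coerced to
#' ascending order (flipping the data as needed) and longitudes on 0..360 are
#' rewrapped to -180..180. Masked (cloud/land) cells are `NA`.
#'
#' @param lon,lat strictly monotonic axes, degrees.
#' @param time numeric time axis (days since an arbitrary epoch).
#' @param data array `(lon, lat, time)` (a matrix is taken as a single time).
#' @param species tracer species tag, `"POC"` or `"PON"`.
#' @param units tracer units, `"mmol_m3"` (default) or `"umol_m3"`.
#' @return A `tracer_grid` object.
#' @export
tracer_grid <- function(lon, lat, time, data, species = c("POC", "PON"),
                        units = c("mmol_m3", "umol_m3")) {
  species <- match.arg(species)
  units <- match.arg(units)
  g <- new_grid("tracer_grid", lon, lat, time, list(tracer = data))
  if (any(g$tracer < 0, na.rm = TRUE))
    stop("tracer concentrations must be non-negative where unmasked")
  g$species <- species
  g$units <- units
  g
}

#' @rdname tracer_grid
#' @param u,v eastward and northward velocity, m/s, arrays `(lon, lat, time)`.
#' @export
velocity_grid <- function(lon, lat, time, u, v) {
  new_grid("velocity_grid", lon, lat, time, list(u = u, v = v))
}

#' @rdname tracer_grid
#' @param eta sea-surface height, m, array `(lon, lat, time)`.
#' @export
ssh_grid <- function(lon, lat, time, eta) {
  new_grid("ssh_grid", lon, lat, time, list(eta = eta))
}

new_grid <- function(cls, lon, lat, time, vars) {
  lon <- as.numeric(lon); lat <- as.numeric(lat); time <- as.numeric(time)
  vars <- lapply(vars, function(a) {
    if (is.matrix(a)) a <- array(a, dim = c(dim(a), 1L))
    if (length(dim(a)) != 3L) stop("grid data must be (lon, lat, time)")
    if (!all(dim(a) == c(length(lon), length(lat), length(time))))
      stop("data dimensions do not match axes")
    a
  })
  if (length(lon) > 1 && all(diff(lon) < 0)) {
    lon <- rev(lon)
    vars <- lapply(vars, function(a) a[rev(seq_along(lon)), , , drop = FALSE])
  }
  if (any(lon > 180)) {  # rewrap 0..360 -> -180..180
    lon2 <- ifelse(lon > 180, lon - 360, lon)
    o <- order(lon2)
    lon <- lon2[o]
    vars <- lapply(vars, function(a) a[o, , , drop = FALSE])
  }
  if (length(lat) > 1 && all(diff(lat) < 0)) {
    vars <- lapply(vars, function(a) a[, rev(seq_along(lat)), , drop = FALSE])
    lat <- rev(lat)
  }
  if (any(diff(lon) <= 0) || any(diff(lat) <= 0))
    stop("lon and lat axes must be strictly monotonic")
  if (length(time) > 1 && any(diff(time) <= 0))
    stop("time axis must be strictly increasing")
  structure(c(list(lon = lon, lat = lat, time = time), vars), class = cls)
}

grid_slice <- function(g, var, it) {
  matrix(g[[var]][, , it], nrow = length(g$lon))
}

#' Write a gridded field to a CF-style NetCDF file
#'
#' Dimensions `lon`, `lat`, `time` with `units` attributes; variables `poc` or
#' `pon` (mmol m-3), `u`/`v` (m s-1) or `ssh` (m) depending on the grid class.
#' Masked cells are written as the fill value.
#'
#' @param g a [tracer_grid()], [velocity_grid()] or [ssh_grid()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_grid <- function(g, path) {
  dlon <- ncdf4::ncdim_def("lon", "degrees_east", g$lon)
  dlat <- ncdf4::ncdim_def("lat", "degrees_north", g$lat)
  dtim <- ncdf4::ncdim_def("time", "days since 2000-01-01", g$time,
                           unlim = TRUE)
  fill <- -9999
  dims <- list(dlon, dlat, dtim)
  if (inherits(g, "tracer_grid")) {
    nm <- tolower(g$species)
    un <- if (g$units == "mmol_m3") "mmol m-3" else "umol m-3"
    vars <- list(ncdf4::ncvar_def(nm, un, dims, fill, prec = "double"))
    data <- list(g$tracer)
  } else if (inherits(g, "velocity_grid")) {
    vars <- list(ncdf4::ncvar_def("u", "m s-1", dims, fill, prec = "double"),
                 ncdf4::ncvar_def("v", "m s-1", dims, fill, prec = "double"))
    data <- list(g$u, g$v)
  } else if (inherits(g, "ssh_grid")) {
    vars <- list(ncdf4::ncvar_def("ssh", "m", dims, fill, prec = "double"))
    data <- list(g$eta)
  } else stop("unknown grid class")
  nc <- ncdf4::nc_create(path, vars)
  on.exit(ncdf4::nc_close(nc))
  for (k in seq_along(vars)) {
    d <- data[[k]]
    d[is.na(d)] <- fill
    ncdf4::ncvar_put(nc, vars[[k]], d)
  }
  invisible(path)
}

#' Read a gridded field from a CF-style NetCDF file
#'
#' Validates that `lon`, `lat`, `time` dimensions exist and that every data
#' variable carries a `units` attribute. Fill values are masked to `NA`,
#' descending axes are returned ascending (with data reordered) and 0..360
#' longitudes are rewrapped to -180..180.
#'
#' @param path NetCDF file path.
#' @param variable which field to read: `"poc"`, `"pon"`, `"velocity"`
#'   (reads `u` and `v`) or `"ssh"`.
#' @return The corresponding grid object.
#' @export
read_grid <- function(path, variable = c("poc", "pon", "velocity", "ssh")) {
  variable <- match.arg(variable)
  if (!file.exists(path)) stop("no such file: ", path)
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  for (ax in c("lon", "lat", "time"))
    if (!ax %in% names(nc$dim)) stop("missing dimension '", ax, "' in ", path)
  lon <- nc$dim$lon$vals
  lat <- nc$dim$lat$vals
  time <- nc$dim$time$vals
  get <- function(nm) {
    if (!nm %in% names(nc$var)) stop("missing variable '", nm, "' in ", path)
    un <- ncdf4::ncatt_get(nc, nm, "units")
    if (!un$hasatt) stop("variable '", nm, "' has no units attribute")
    a <- ncdf4::ncvar_get(nc, nm, collapse_degen = FALSE)
    if (length(dim(a)) == 2L) a <- array(a, dim = c(dim(a), 1L))
    list(data = a, units = un$value)
  }
  if (variable %in% c("poc", "pon")) {
    v <- get(variable)
    un <- if (grepl("umol", v$units)) "umol_m3" else "mmol_m3"
    tracer_grid(lon, lat, time, v$data, species = toupper(variable),
                units = un)
  } else if (variable == "velocity") {
    u <- get("u"); v <- get("v")
    velocity_grid(lon, lat, time, u$data, v$data)
  } else {
    e <- get("ssh")
    ssh_grid(lon, lat, time, e$data)
  }
}
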