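#' Construct a nutrient concentration profile
#'
#' @param species `"nitrate"` or `"ammonium"`.
#' @param depth depths, m, positive downward, strictly increasing.
#' @param conc concentrations. Internal currency is \eqn{\mu}mol m\eqn{^{-3}};
#'   note 1 nM = 1 \eqn{\mu}mol m\eqn{^{-3}}, so `"nM"` input needs no
#'   conversion and `"mmol_m3"` is multiplied by 1000.
#' @param cast_id,time identifiers.
#' @param units one of `"umol_m3"`, `"nM"`, `"mmol_m3"`.
#' @return A `nutrient_profile` data frame (`depth`, `conc` in umol/m3).
#' @export
nutrient_profile <- function(species = c("nitrate", "ammonium"), depth, conc,
                             cast_id = "cast", time = NA,
                             units = c("umol_m3", "nM", "mmol_m3")) {
  species <- match.arg(species)
  units <- match.arg(units)
  conc <- as.numeric(conc) * switch(units, umol_m3 = 1, nM = 1, mmol_m3 = 1e3)
  if (length(depth) != length(conc)) stop("depth and conc lengths differ")
  if (any(diff(depth) <= 0)) stop("depth must be strictly increasing")
  if (any(conc < 0)) stop("concentrations must be non-negative")
  structure(data.frame(depth = as.numeric(depth), conc = conc),
            species = species, cast_id = cast_id, time = time,
            class = c("nutrient_profile", "data.frame"))
}

#' Vertical nutrient gradient over a depth layer
#'
#' Ordinary least-squares slope of concentration against depth over the
#' samples inside the layer (positive gradient = concentration increasing
#' downward). If fewer than two samples fall inside, the nearest bracketing
#' samples above and below are included; with exactly two samples the OLS
#' slope reduces to the finite difference.
#'
#' @param p a [nutrient_profile()].
#' @param layer numeric length-2, `c(top, bottom)` in m.
#' @return Gradient in \eqn{\mu}mol m\eqn{^{-4}}.
#' @export
layer_gradient <- function(p, layer) {
  stopifnot(length(layer) == 2L, layer[1] < layer[2])
  inside <- p$depth >= layer[1] & p$depth <= layer[2]
  idx <- which(inside)
  if (length(idx) < 2L) {
    above <- which(p$depth < layer[1])
    below <- which(p$depth > layer[2])
    if (length(above)) idx <- c(max(above), idx)
    if (length(below)) idx <- c(idx, min(below))
  }
  if (length(idx) < 2L)
    stop("need at least 2 samples within or bracketing the layer")
  z <- p$depth[idx]; c0 <- p$conc[idx]
  sum((z - mean(z)) * (c0 - mean(c0))) / sum((z - mean(z))^2)
}

#' Turbulent diffusive nutrient flux across a layer boundary
#'
#' With depth positive downward, the upward flux into the overlying layer is
#' \eqn{F = K_z \, d C/dz \times 86400} in \eqn{\mu}mol N m\eqn{^{-2}}
#' d\eqn{^{-1}}; this is the discrete form of \eqn{F_z = -K_z\,d[NO_3^-]/dz}
#' under the usual z-positive-up sign convention. Nutrient increasing with
#' depth and positive \eqn{K_z} therefore give a positive (upward, into the
#' euphotic zone) flux.
#'
#' @param kz vertical eddy diffusivity, m\eqn{^2} s\eqn{^{-1}}, >= 0.
#' @param gradient d(conc)/dz, \eqn{\mu}mol m\eqn{^{-4}}, z positive downward.
#' @param layer optional `c(top, bottom)` annotation, m.
#' @return A one-row data frame of class `vertical_flux_estimate` with
#'   `layer_top`, `layer_bottom`, `kz`, `gradient` and `flux`
#'   (\eqn{\mu}mol N m\eqn{^{-2}} d\eqn{^{-1}}, positive upward).
#' @export
#' @examples
#' diffusive_flux(1e-4, 0.1157)$flux  # ~1 umol N m-2 d-1
diffusive_flux <- function(kz, gradient, layer = c(NA_real_, NA_real_)) {
  if (!is.finite(kz) || kz < 0) stop("kz must be non-negative and finite")
  structure(data.frame(layer_top = layer[1], layer_bottom = layer[2],
                       kz = kz, gradient = gradient,
                       flux = kz * gradient * 86400),
            class = c("vertical_flux_estimate", "data.frame"))
}

#' Diffusive nitrate flux across a boundary from a diffusivity profile
#'
#' Convenience wrapper combining [layer_gradient()] and [diffusive_flux()]:
#' the gradient is fit over a window centred on the boundary and \eqn{K_z} is
#' the geometric mean of the diffusivity-profile bins overlapping the window.
#'
#' @param p a [nutrient_profile()] (or list of profiles, whose gradients are
#'   averaged).
#' @param kz_profile a `diffusivity_profile` from [average_kz()].
#' @param boundary boundary depth, m.
#' @param window window height, m (default 20, centred on the boundary).
#' @return A `vertical_flux_estimate` (see [diffusive_flux()]).
#' @export
boundary_nitrate_flux <- function(p, kz_profile, boundary, window = 20) {
  layer <- boundary + c(-0.5, 0.5) * window
  profs <- if (inherits(p, "nutrient_profile")) list(p) else p
  grad <- mean(vapply(profs, layer_gradient, numeric(1), layer = layer))
  ov <- kz_profile$depth_top < layer[2] & kz_profile$depth_bottom > layer[1]
  if (!any(ov)) stop("diffusivity profile does not cover the layer")
  kz <- exp(mean(log(kz_profile$kz_geomean[ov])))
  diffusive_flux(kz, grad, layer)
}
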