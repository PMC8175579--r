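#' Photo-fixation model parameters
#'
#' Parameters of the light-saturation (P-I) curve used to convert trichome
#' abundance and per-trichome chlorophyll into chlorophyll-specific
#' N\eqn{_2}-fixation rates. The curve is exponential saturation without
#' photoinhibition: \eqn{F(E) = F_{max}\,(1 - e^{-\alpha E / F_{max}})}.
#' Coefficient sets from culture studies can be dropped in unchanged.
#'
#' @param fmax maximum chlorophyll-specific fixation rate,
#'   \eqn{\mu}mol N (\eqn{\mu}g chl)\eqn{^{-1}} h\eqn{^{-1}}.
#' @param alpha initial slope, \eqn{\mu}mol N (\eqn{\mu}g chl)\eqn{^{-1}}
#'   h\eqn{^{-1}} per (\eqn{\mu}mol photons m\eqn{^{-2}} s\eqn{^{-1}}).
#' @param photoperiod daylight hours over which fixation occurs (default 12;
#'   dark fixation is assumed zero).
#' @param temperature culture/in-situ temperature the coefficients refer to,
#'   deg C (default 26; annotation only).
#' @return A `photofixation_params` list.
#' @export
photofixation_params <- function(fmax, alpha, photoperiod = 12,
                                 temperature = 26) {
  if (missing(fmax) || missing(alpha))
    stop("fmax and alpha are required (no universal default exists)")
  if (fmax <= 0 || alpha <= 0) stop("fmax and alpha must be positive")
  structure(list(fmax = fmax, alpha = alpha, photoperiod = photoperiod,
                 temperature = temperature), class = "photofixation_params")
}

#' Volumetric N2-fixation rate profile from trichome counts
#'
#' Combines a trichome abundance/chlorophyll profile with a PAR profile
#' (interpolated linearly onto the trichome depths) through the
#' photo-fixation curve:
#' rate(z) = abundance(z) x 1000 [tr m-3] x chl_per_trichome x 1e-3
#' [ug chl tr-1] x Fmax (1 - exp(-alpha E(z)/Fmax)) x photoperiod.
#'
#' @param tp data frame with `depth` (m), `abundance` (trichomes/L, 0 or
#'   more) and `chl_per_trichome` (ng chl a per trichome, positive).
#' @param par data frame with `depth` (m) and `irradiance`
#'   (\eqn{\mu}mol photons m\eqn{^{-2}} s\eqn{^{-1}}, non-increasing with
#'   depth).
#' @param params a [photofixation_params()].
#' @return Data frame `depth`, `rate` (\eqn{\mu}mol N m\eqn{^{-3}}
#'   d\eqn{^{-1}}).
#' @export
fixation_rate_profile <- function(tp, par, params) {
  if (any(tp$abundance < 0)) stop("abundance must be non-negative")
  if (any(tp$chl_per_trichome <= 0)) stop("chl_per_trichome must be positive")
  if (any(par$irradiance < 0)) stop("irradiance must be non-negative")
  if (max(tp$depth) < min(par$depth) || min(tp$depth) > max(par$depth))
    stop("trichome and PAR profiles do not overlap in depth")
  e <- stats::approx(par$depth, par$irradiance, xout = tp$depth, rule = 2)$y
  light <- params$fmax * (1 - exp(-params$alpha * e / params$fmax))
  rate <- tp$abundance * 1000 * tp$chl_per_trichome * 1e-3 * light *
    params$photoperiod
  data.frame(depth = tp$depth, rate = rate)
}

#' Depth-integrate a volumetric rate profile
#'
#' Trapezoidal integration between `z_top` and `z_bottom`, with linear
#' interpolation of the profile at the integration limits.
#'
#' @param profile data frame with `depth` and `rate` columns.
#' @param z_top,z_bottom integration limits, m, inside the profile span.
#' @return Areal rate, \eqn{\mu}mol N m\eqn{^{-2}} d\eqn{^{-1}}.
#' @export
integrate_fixation <- function(profile, z_top, z_bottom) {
  if (z_top >= z_bottom) stop("z_top must be shallower than z_bottom")
  if (z_top < min(profile$depth) - 1e-9 ||
      z_bottom > max(profile$depth) + 1e-9)
    stop("integration limits outside the profile span")
  z <- sort(unique(c(z_top, z_bottom,
                     profile$depth[profile$depth > z_top &
                                     profile$depth < z_bottom])))
  r <- stats::approx(profile$depth, profile$rate, xout = z)$y
  sum(diff(z) * (r[-1] + r[-length(r)]) / 2)
}

#' Potential nitrate production by nitrification
#'
#' Product of an ammonium stock and an ammonium-specific nitrification rate,
#' giving the potential volumetric nitrate source.
#'
#' @param nh4 ammonium concentration, \eqn{\mu}mol m\eqn{^{-3}}, >= 0.
#' @param specific_rate ammonium-specific nitrification rate, d\eqn{^{-1}},
#'   >= 0. Oligotrophic literature values span roughly 0.02-0.5.
#' @return Potential nitrate source, \eqn{\mu}mol N m\eqn{^{-3}} d\eqn{^{-1}}.
#' @export
#' @examples
#' nitrification_potential(60, 0.5)  # 30
nitrification_potential <- function(nh4, specific_rate) {
  if (any(nh4 < 0) || any(specific_rate < 0))
    stop("nh4 and specific_rate must be non-negative")
  nh4 * specific_rate
}
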