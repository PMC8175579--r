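#' Standard mesozooplankton size classes (mm)
#' @export
zoop_size_classes <- c("0.2-0.5", "0.5-1", "1-2", "2-5", ">5")

#' Construct a size-fractionated zooplankton tow
#'
#' Carbon biomass by sieve size class from an oblique net tow, with the mean
#' individual carbon content per class used to convert biomass to abundance.
#'
#' @param tow_id identifier.
#' @param phase `"day"` or `"night"`.
#' @param carbon_biomass mg C m\eqn{^{-2}} per size class (length 5, ordered
#'   as [zoop_size_classes]).
#' @param mean_individual_carbon mg C per individual, per class (positive).
#' @param size_class class labels (default [zoop_size_classes]).
#' @return A `size_fraction_tow` data frame.
#' @export
size_fraction_tow <- function(tow_id, phase = c("day", "night"),
                              carbon_biomass, mean_individual_carbon,
                              size_class = zoop_size_classes) {
  phase <- match.arg(phase)
  if (length(carbon_biomass) != 5L || length(mean_individual_carbon) != 5L ||
      length(size_class) != 5L)
    stop("a tow must have exactly five size classes")
  if (any(carbon_biomass < 0)) stop("biomass must be non-negative")
  if (any(mean_individual_carbon <= 0))
    stop("mean individual carbon must be positive")
  structure(data.frame(size_class = size_class,
                       carbon_biomass = carbon_biomass,
                       mean_individual_carbon = mean_individual_carbon),
            tow_id = tow_id, phase = phase,
            class = c("size_fraction_tow", "data.frame"))
}

#' Allometric excretion parameters
#'
#' Coefficients of the ln-linear ammonium excretion regression
#' \eqn{\ln E = a_0 + a_1 \ln C_{ind} + a_2 T}, where \eqn{C_{ind}} is
#' individual body carbon (mg C) and E is per-individual excretion
#' (\eqn{\mu}mol N individual\eqn{^{-1}} h\eqn{^{-1}}). The coefficients are
#' configuration: pass the published regression appropriate to the taxa and
#' currency in use.
#'
#' @param a0,a1,a2 regression coefficients (required).
#' @param depth_temperature temperature at migrant residence depth, deg C
#'   (default 11, representative of 300-500 m in subtropical basins).
#' @param hours_at_depth daytime hours spent at depth (default 12).
#' @return An `excretion_params` list.
#' @export
excretion_params <- function(a0, a1, a2, depth_temperature = 11,
                             hours_at_depth = 12) {
  if (missing(a0) || missing(a1) || missing(a2))
    stop("excretion coefficients a0, a1, a2 are required")
  if (depth_temperature < -2 || depth_temperature > 35)
    stop("depth_temperature outside -2..35 deg C")
  if (hours_at_depth <= 0 || hours_at_depth > 24)
    stop("hours_at_depth must be in (0, 24]")
  structure(list(a0 = a0, a1 = a1, a2 = a2,
                 depth_temperature = depth_temperature,
                 hours_at_depth = hours_at_depth),
            class = "excretion_params")
}

#' Migrant biomass from paired day/night tows
#'
#' Per size class, the diel-migrant carbon is the night-minus-day biomass
#' difference, clipped at zero (a daytime excess is not a migrant signal).
#'
#' @param day,night `size_fraction_tow` objects sharing the same classes.
#' @return Named numeric vector of migrant carbon (mg C m\eqn{^{-2}}) per
#'   class.
#' @export
migrant_biomass <- function(day, night) {
  if (!identical(day$size_class, night$size_class))
    stop("day and night tows must share the same size classes")
  m <- pmax(0, night$carbon_biomass - day$carbon_biomass)
  names(m) <- day$size_class
  m
}

#' Active nitrogen transport by migrant excretion at depth
#'
#' Converts per-class migrant carbon to individuals
#' (migrant C / individual C), applies the allometric per-individual
#' excretion rate at the residence-depth temperature, and accumulates over
#' the daytime hours at depth:
#' flux = sum over classes of individuals x exp(a0 + a1 ln(C_ind) + a2 T)
#' x hours_at_depth.
#'
#' @param migrant named vector of migrant carbon per class, mg C
#'   m\eqn{^{-2}} (from [migrant_biomass()]).
#' @param params an [excretion_params()].
#' @param indiv_carbon mean individual carbon per class, mg C (positive).
#' @return Areal active transport, \eqn{\mu}mol N m\eqn{^{-2}} d\eqn{^{-1}}.
#' @export
migrant_excretion <- function(migrant, params, indiv_carbon) {
  if (!inherits(params, "excretion_params"))
    stop("params must be an excretion_params object")
  if (length(indiv_carbon) != length(migrant))
    stop("indiv_carbon must match migrant classes")
  if (any(indiv_carbon <= 0)) stop("individual carbon must be positive")
  inds <- migrant / indiv_carbon  # individuals m-2
  e <- exp(params$a0 + params$a1 * log(indiv_carbon) +
             params$a2 * params$depth_temperature)  # umol N ind-1 h-1
  sum(inds * e * params$hours_at_depth)
}
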