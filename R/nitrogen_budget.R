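#' Nutrient uptake rate from a 15N tracer incubation
#'
#' Standard isotope-dilution uptake calculation: the particulate-nitrogen
#' production rate is the end-point PN times the fractional enrichment of the
#' particles relative to the labelled substrate pool, divided by the
#' incubation duration.
#'
#' @param pn particulate N at the end of the incubation,
#'   \eqn{\mu}mol m\eqn{^{-3}}.
#' @param atom_percent_final atom% 15N of the particles at the end.
#' @param atom_percent_enriched atom% 15N of the substrate pool after the
#'   spike.
#' @param duration incubation length, d.
#' @param atom_percent_natural natural-abundance atom% 15N (default 0.3663).
#' @return Uptake rate, \eqn{\mu}mol N m\eqn{^{-3}} d\eqn{^{-1}}.
#' @export
#' @examples
#' tracer_uptake_rate(100, 1.3663, 10.3663, 1)  # 10
tracer_uptake_rate <- function(pn, atom_percent_final, atom_percent_enriched,
                               duration, atom_percent_natural = 0.3663) {
  if (duration <= 0) stop("duration must be positive")
  if (atom_percent_final < atom_percent_natural)
    stop("final atom% below natural abundance")
  den <- atom_percent_enriched - atom_percent_natural
  if (den <= 0) stop("substrate pool not enriched above natural abundance")
  pn * (atom_percent_final - atom_percent_natural) / den / duration
}

#' f-ratio: new production as a fraction of total production
#'
#' @param new_production NP, \eqn{\mu}mol N m\eqn{^{-2}} d\eqn{^{-1}}, >= 0.
#' @param regenerated_production RP, same units, >= 0.
#' @return NP / (NP + RP), in the unit interval.
#' @export
#' @examples
#' f_ratio(70, 930)  # 0.07
f_ratio <- function(new_production, regenerated_production) {
  if (new_production < 0 || regenerated_production < 0)
    stop("production terms must be non-negative")
  if (new_production + regenerated_production == 0)
    stop("f-ratio undefined when NP and RP are both zero")
  new_production / (new_production + regenerated_production)
}

#' Two-endmember nitrogen-isotope endmembers
#'
#' delta15N signatures (per mil vs atmospheric N2) of the candidate source
#' pools and of the exported nitrogen. N2-fixation introduces nitrogen near
#' atmospheric composition; upward-mixed subsurface nitrate carries the
#' subsurface signature.
#'
#' @param delta_nitrate subsurface nitrate delta15N (typically 2.0-3.8).
#' @param delta_fixation newly fixed N delta15N (typically -2-0).
#' @param delta_export sinking + actively transported N delta15N.
#' @return An `isotope_endmembers` list.
#' @export
isotope_endmembers <- function(delta_nitrate, delta_fixation, delta_export) {
  if (delta_nitrate == delta_fixation)
    stop("endmembers must differ for a two-endmember balance")
  structure(list(delta_nitrate = delta_nitrate,
                 delta_fixation = delta_fixation,
                 delta_export = delta_export), class = "isotope_endmembers")
}

#' Fraction of export nitrogen supplied by N2-fixation (isotope balance)
#'
#' Mass balance requires the export delta15N to equal that of the source
#' mixture, so the fixation fraction is
#' \eqn{f = (\delta_{NO3} - \delta_{exp}) / (\delta_{NO3} - \delta_{fix})},
#' clipped to the unit interval (the raw value is attached as attribute
#' `"raw"` for diagnostics).
#'
#' @param e an [isotope_endmembers()].
#' @return Fixation fraction in the unit interval.
#' @export
isotope_fixation_fraction <- function(e) {
  raw <- (e$delta_nitrate - e$delta_export) /
    (e$delta_nitrate - e$delta_fixation)
  structure(min(1, max(0, raw)), raw = raw)
}

#' Percent of export supported by each nitrogen source
#'
#' Each named source flux is expressed as a percentage of the measured
#' export; the residual export not met by local sources is the lateral
#' requirement.
#'
#' @param export measured export flux, \eqn{\mu}mol N m\eqn{^{-2}}
#'   d\eqn{^{-1}}, > 0.
#' @param sources named numeric vector of local source fluxes, same units,
#'   >= 0.
#' @return A list with `shares_pct` (per source), `lateral_required`
#'   (\eqn{\mu}mol N m\eqn{^{-2}} d\eqn{^{-1}}) and `lateral_share_pct`.
#' @export
#' @examples
#' support_fractions(462, c(vertical = 1, fixation = 2.8))
support_fractions <- function(export, sources) {
  if (export <= 0) stop("export must be positive")
  if (any(sources < 0)) stop("sources must be non-negative")
  lateral <- max(0, export - sum(sources))
  list(shares_pct = 100 * sources / export,
       lateral_required = lateral,
       lateral_share_pct = 100 * lateral / export)
}

#' Assemble the euphotic-zone nitrogen budget
#'
#' Collates measured export with the computed local new-nitrogen sources
#' per layer (upper euphotic zone, UEZ; lower euphotic zone, LEZ) and
#' derives the lateral requirement and support fractions.
#'
#' @param export_uez,export_lez measured sinking-PON export at the UEZ and
#'   LEZ base, \eqn{\mu}mol N m\eqn{^{-2}} d\eqn{^{-1}}.
#' @param vertical_flux_uez,vertical_flux_lez turbulent nitrate flux across
#'   the UEZ and LEZ lower boundaries (negative values are treated as zero
#'   supply).
#' @param n2_fixation UEZ-integrated N2-fixation.
#' @param active_transport migrant active transport (an export-side term,
#'   reported alongside sinking export).
#' @param isotopes optional [isotope_endmembers()] for the fixation-fraction
#'   diagnostic.
#' @return A `nitrogen_budget` object: `table` (term, layer, value,
#'   provenance, share_pct), per-layer [support_fractions()] under `uez` and
#'   `lez`, and `isotope_fixation_fraction` if endmembers were given.
#' @export
assemble_budget <- function(export_uez, export_lez,
                            vertical_flux_uez, vertical_flux_lez,
                            n2_fixation, active_transport = 0,
                            isotopes = NULL) {
  need <- c(export_uez, export_lez, vertical_flux_uez, vertical_flux_lez,
            n2_fixation)
  if (any(is.na(need))) stop("missing required budget term")
  uez <- support_fractions(export_uez,
                           c(vertical = max(0, vertical_flux_uez),
                             fixation = n2_fixation))
  lez <- support_fractions(export_lez,
                           c(vertical = max(0, vertical_flux_lez),
                             fixation = n2_fixation))
  tab <- rbind(
    data.frame(term = "export", layer = c("UEZ", "LEZ"),
               value = c(export_uez, export_lez), provenance = "measured",
               share_pct = 100),
    data.frame(term = "vertical_flux", layer = c("UEZ", "LEZ"),
               value = c(vertical_flux_uez, vertical_flux_lez),
               provenance = "computed",
               share_pct = c(uez$shares_pct["vertical"],
                             lez$shares_pct["vertical"])),
    data.frame(term = "n2_fixation", layer = c("UEZ", "LEZ"),
               value = n2_fixation, provenance = "computed",
               share_pct = c(uez$shares_pct["fixation"],
                             lez$shares_pct["fixation"])),
    data.frame(term = "lateral_required", layer = c("UEZ", "LEZ"),
               value = c(uez$lateral_required, lez$lateral_required),
               provenance = "computed",
               share_pct = c(uez$lateral_share_pct, lez$lateral_share_pct)),
    data.frame(term = "active_transport", layer = "export",
               value = active_transport, provenance = "computed",
               share_pct = NA_real_))
  rownames(tab) <- NULL
  out <- list(table = tab, uez = uez, lez = lez)
  if (!is.null(isotopes))
    out$isotope_fixation_fraction <- isotope_fixation_fraction(isotopes)
  structure(out, class = "nitrogen_budget")
}

#' @export
print.nitrogen_budget <- function(x, ...) {
  cat("Euphotic-zone nitrogen budget (umol N m-2 d-1)\n")
  print(x$table, row.names = FALSE, digits = 4)
  cat(sprintf("Lateral share: UEZ %.1f%%, LEZ %.1f%%\n",
              x$uez$lateral_share_pct, x$lez$lateral_share_pct))
  if (!is.null(x$isotope_fixation_fraction))
    cat(sprintf("Isotope-balance fixation fraction: %.3f\n",
                as.numeric(x$isotope_fixation_fraction)))
  invisible(x)
}
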