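Package: nitrobudget
Title: Euphotic-Zone Nitrogen Budgets for Oligotrophic Ocean Regions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for constructing new-nitrogen budgets of stratified,
    oligotrophic upper-ocean regions such as the open Gulf of Mexico.
    Estimates vertical eddy diffusivity from CTD density profiles by
    Thorpe-scale overturn analysis, turbulent diffusive nitrate fluxes
    across euphotic-zone boundaries, lateral organic-nitrogen transport
    into a polygonal control volume from gridded ocean-colour and surface
    current fields (with mesoscale eddy attribution from sea-surface
    height), Trichodesmium dinitrogen fixation from trichome counts via a
    light-saturation photo-fixation model, active nitrogen transport by
    diel vertically migrating zooplankton from paired day/night tows, and
    synthesizes these against measured export into support fractions,
    f-ratios and a two-endmember nitrogen-isotope mass balance. A seeded
    synthetic-ocean generator emulates the cruise and satellite data so
    the whole pipeline runs and is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    ncdf4,
    pracma,
    sp,
    yaml
Suggests:
    testthat (>= 3.0.0),
    geosphere,
    jsonlite,
    knitr
Config/testthat/edition: 3
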