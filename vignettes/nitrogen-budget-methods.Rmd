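---
title: "Methods: euphotic-zone nitrogen budgets from turbulence, transport and plankton observations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: euphotic-zone nitrogen budgets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nitrobudget)
```

## The problem

Stratified, oligotrophic open-ocean regions such as the deep-water Gulf of
Mexico present a budget paradox: surface nitrate and ammonium sit near
detection limits, turbulent mixing is weak, and dinitrogen fixation by
*Trichodesmium* is modest — yet sediment traps catch hundreds of µmol of
sinking particulate organic nitrogen (PON) per square metre per day. Because
mass must balance over sufficiently large space and time scales, export of
that magnitude requires an external nitrogen supply. `nitrobudget`
implements the accounting needed to test whether the *local* new-nitrogen
sources (turbulent nitrate flux from below, N~2~-fixation, active transport
by vertical migrators) can pay for the measured export, and to estimate the
*lateral* supply of organic nitrogen into a control volume from gridded
ocean-colour and surface-current fields. The budget currency throughout is
µmol N m^-2^ d^-1^; depth is positive downward.

The euphotic zone is split into an upper layer (UEZ, 0–60 m) and a lower
layer (LEZ, from 60 m to the euphotic-zone base near 110–150 m), because the
two layers have distinct light, nutrient and export regimes.

## Vertical mixing: Thorpe-scale analysis

A CTD density profile through a turbulent patch contains gravitationally
unstable inversions. Sorting the potential-density profile
$\sigma_\theta(z)$ into ascending order restores stability; the vertical
distance each sample moves is its Thorpe displacement $d_i$, and the rms
displacement over a contiguous overturning patch is the Thorpe scale $L_T$.
The sort is stable with index-order tie-breaking, so equal densities yield
zero displacement, and displacements sum to zero over the full profile and
over every complete patch — both properties are asserted in the test suite
against a brute-force selection-sort oracle.

Patches are maximal runs over which the cumulative displacement departs
from zero and returns to zero. Two rejection rules suppress sensor noise:
a patch must span at least `min_patch_samples` (default 3) samples and a
density range of at least `noise_threshold` (default 0.002 kg m^-3^).
Accepted patches are converted to mixing quantities through the
Ozmidov–Thorpe proportionality and the Osborn relation:

$$\varepsilon = (a L_T)^2 N^3, \qquad
  K_z = \Gamma\,\varepsilon / N^2 = \Gamma a^2 L_T^2 N,$$

with mixing efficiency $\Gamma = 0.2$ and Ozmidov ratio $a = 0.8$ — the
community-standard constants for this method; both are configuration
(`mixing_params()`). The buoyancy frequency $N$ is computed per patch from
the sorted (statically stable) profile by endpoint difference; a linear-fit
alternative is selectable (`n2_method = "fit"`). Patches with non-positive
$N^2$ are rejected with a warning. Raw Seabird-style artefacts are handled
before sorting: samples from pressure reversals are dropped (a sample must
be deeper than all samples before it) and single-sample spikes further than
`despike_k` × `noise_threshold` from a running window median are removed.
The despiking specifics are this package's choice; processing
recommendations for raw CTD data vary and the exact scheme is exposed as
configuration.

Per cast, patch diffusivities are mapped onto uniform depth bins
(displacement-weighted mean where patches overlap a bin); bins without
overturns receive a background floor of 10^-6^ m^2^ s^-1^ rather than zero,
both because observed diffusivity minima are of that order and because the
cross-cast average is a *geometric* mean — the distribution of $K_z$ across
repeated casts is close to log-normal, and a single zero would annihilate
the product. The number of contributing casts is recorded per bin.

## Vertical nitrate flux

The turbulent diffusive flux across a depth horizon follows the gradient
law $F_z = -K_z \, \partial[\mathrm{NO_3^-}]/\partial z$ (z positive up);
with depth positive downward, as used internally, the upward flux into the
overlying layer is `kz * gradient * 86400` µmol N m^-2^ d^-1^, so nitrate
increasing with depth plus positive $K_z$ gives a positive (upward) supply.
The gradient is the OLS slope of concentration against depth over a 20-m
window centred on the boundary (the differencing scheme is not standardized
in field practice; the window is configuration, and with exactly two
samples the slope reduces to the finite difference). $K_z$ at the boundary
is the geometric mean of the diffusivity-profile bins overlapping the
window. Concentration is carried in µmol m^-3^; 1 nM ≡ 1 µmol m^-3^, so
nanomolar field data need no conversion.

## Lateral transport into a control volume

Surface particulate organic carbon (POC) composites are converted to PON by
Redfield stoichiometry (106:16 C:N, molar), block-averaged to ~8-km cells
to suppress retrieval noise, and combined with a surface-current product
mapped onto the tracer grid by bilinear spatial and linear temporal
interpolation. The control volume is a lon/lat polygon extended uniformly
over the upper `H` = 55 m (surface tracer is assumed vertically uniform
over that extent, which treats the ocean-colour value as representative of
the UEZ; `H` is configuration).

The polygon is rasterised to tracer cells, and the net flux is a sum over
the grid-cell faces separating inside from outside cells:
$-(\mathbf{u}\cdot\hat n)\, C_{face}\, L \, H$ per face, divided by the
cell-sum surface area and converted to µmol N m^-2^ d^-1^. Face
concentrations use the centred mean of the two adjacent cells (upwind
selectable); masked (cloud/land) neighbours fall back to the unmasked cell,
and a face with both neighbours masked contributes zero and increments a
coverage diagnostic. Geometry is spherical (Earth radius 6371 km):
meridional faces have length $R\,\Delta\varphi$ and zonal faces
$R\cos\varphi\,\Delta\lambda$ — at 25°N a 1/3° cell is ~10% anisotropic,
which planar geometry would ignore.

One discretisation detail matters for conservation. Through zonal (N/S)
faces the normal transport is computed by averaging $v\cos\varphi$ at the
two adjacent cell centres and multiplying by $R\,\Delta\lambda$, rather
than averaging $v$ itself and multiplying by the face length. Under this
flux-form averaging, a velocity field derived from a streamfunction by
central differences (e.g., the generator's geostrophic flow) has exactly
zero discrete divergence, so a uniform tracer in such a flow produces a net
flux at rounding error — the conservation property is exact by
construction, not approximate. Plain averaging of $v$ cannot cancel the
$\cos\varphi$ metric and would leave a spurious residual. The same face
sums satisfy a discrete divergence theorem (boundary sum equals the summed
per-cell divergence over interior cells), which the tests verify to
10^-10^.

Medians and interquartile ranges over the composite time series use linear
interpolation of order statistics (type-7 quantiles).

### Eddy detection and attribution

Mesoscale eddies are identified from sea-surface height: for each local SSH
extremum, the candidate boundaries are the closed SSH contours (level
spacing 0.02 m by default, ≥4 vertices) enclosing that extremum and no
other; the eddy boundary is the candidate with the greatest mean
along-contour surface speed, and polarity follows the extremum sign
(maxima are anticyclonic in the northern hemisphere). This is the
speed-based closed-contour criterion in simplified, single-snapshot form —
no tracking through time is attempted. For a Gaussian SSH anomaly of
e-folding radius $L$ in geostrophic balance, the azimuthal speed
$\propto r e^{-r^2/2L^2}$ peaks exactly at $r = L$, which provides an
analytic target: the detected boundary radius must sit within one grid
cell of $L$. Eddy attribution recomputes the net flux using only boundary
faces whose inside-cell centres fall within any eddy boundary and reports
it as a flux and as a fraction of the total.

## Local sources

**N~2~-fixation.** Trichome counts and per-trichome chlorophyll are
converted to volumetric fixation through a chlorophyll-specific
photosynthesis–irradiance curve with exponential saturation and no
photoinhibition:

$$\mathrm{rate}(z) = A(z)\cdot 10^3 \;\times\; \mathrm{chl}\cdot 10^{-3}
  \;\times\; F_{max}\left(1 - e^{-\alpha E(z)/F_{max}}\right)
  \;\times\; \mathrm{photoperiod},$$

with $A$ in trichomes L^-1^, chl in ng per trichome, $E$ the PAR profile
interpolated onto the trichome depths, and dark (night) fixation assumed
zero so the 12-h photoperiod scales the daily integral. The saturation form
is this package's choice of P–I curve; the published coefficient sets it is
meant to host are laboratory regressions of $F_{max}$ and $\alpha$ versus
temperature, so both are *required* configuration with no universal default
(`photofixation_params()`). Depth integration is trapezoidal with
interpolated endpoints, and the integral is additive over contiguous
ranges (tested).

**Nitrification potential.** Euphotic-zone nitrification regenerates
nitrate from ammonium and can decouple nitrate uptake from new production.
The package reports the exact product of an ammonium stock and an
ammonium-specific rate; with the 60 µmol m^-3^ ammonium typical of these
waters and literature specific rates of 0.02–0.5 d^-1^, the potential
source spans 1.2–30 µmol N m^-3^ d^-1^ (the product at the low rate is
1.2, reported exactly rather than rounded).

**Active transport.** Diel vertical migrators feed in the surface layer at
night and excrete at daytime residence depths. Migrant biomass per size
class is the night-minus-day carbon difference of paired tows, clipped at
zero — a daytime excess is not a migrant signal. Per class, biomass is
converted to individuals via the mean individual carbon, and per-individual
ammonium excretion follows the ln-linear allometric regression
$\ln E = a_0 + a_1 \ln C_{ind} + a_2 T$ evaluated at the 300–500-m
residence temperature (default 11 °C) for the daytime hours at depth
(default 12 h). Which published coefficient set to use (taxon mix, oxygen-
to-nitrogen conversion, body-mass currency) is a genuine degree of freedom,
so the coefficients are required configuration; the shipped example values
(−2.89, 0.76, 0.051) are a representative subtropical epipelagic set, not a
claim about any particular study's choice. Excreted DOM and mortality at
depth are deliberately excluded.

## Budget synthesis

`support_fractions()` expresses each local source as a percentage of the
measured export and defines the lateral requirement as the unexplained
residual (clipped at zero); the percentages are scale-invariant.
`assemble_budget()` collates both layers into a provenance-labelled table.
Two independent diagnostics accompany the budget: the f-ratio
NP/(NP + RP) partitioning production into new and regenerated components,
and a two-endmember δ^15^N mass balance — export δ^15^N must equal the
source mixture, so the fixation share is
$(\delta_{NO_3} - \delta_{exp})/(\delta_{NO_3} - \delta_{fix})$, clipped to
the unit interval with the raw value retained as a diagnostic attribute.
Tracer-incubation uptake rates use the standard isotope-dilution formula
with natural abundance 0.3663 atom% ^15^N (configuration).

## The synthetic ocean

No public accession covers the field campaigns this style of budget is
built from, so the package ships a seeded generator (`sim_config()` and
`gen_*`) whose defaults encode the study conditions rather than convenient
test cases:

* **Casts** (20, within the 14–26 per-experiment range): 0.25-m sampling
  over 0–200 m, background $N^2 = 2\times10^{-5}$ s^-2^, sensor noise SD
  10^-4^ kg m^-3^ (well below the 0.002 rejection threshold), and injected
  overturns built by density-reversing 1–2-m segments — heights chosen so
  patch $K_z = \Gamma a^2 L_T^2 N$ stays near the observed
  10^-6^–10^-4^ m^2^ s^-1^ geometric-mean envelope. Ground-truth patch
  boundaries are recorded for recovery tests.
* **Nutrients**: nitrate ~30 µmol m^-3^ (sub-50-nM) through the euphotic
  zone rising through a logistic nitracline whose midpoint is solved so
  that 0.1 mmol m^-3^ is reached at the configured onset depth (default
  117 m, inside the regional 80–125 m) and ~8 mmol m^-3^ near 150 m
  (inside 2.5–12 µM). This deep-onset shape is what the observations show
  — depressed nitrate *through* the euphotic zone — and it is why the LEZ
  diffusive flux lands in the sub-1 µmol N m^-2^ d^-1^ range while the UEZ
  gradient is indistinguishable from zero. Ammonium is depth-uniform at 60
  µmol m^-3^.
* **Surface fields**: SSH as drifting Gaussian anomalies; velocities
  geostrophic from SSH on an f-plane by the central differences that make
  the flow discretely non-divergent under the flux operator (a β-plane and
  ageostrophic components are out of scope); POC as an offshore background
  (2 mmol m^-3^) plus an exponential northern-coastal gradient (8 mmol
  m^-3^ amplitude, 150-km e-folding), eddy-trapped anomalies, 5% lognormal
  noise and a 3% cloud mask. The default grid is 0.08° (~8 km) over
  92–85°W, 23–28°N with ten 8-day composites; the velocity product can be
  coarsened (e.g., 1/3°) to exercise the regridding path.
* **Plankton**: trichome abundance decaying from 8 tr L^-1^ at the surface
  (12-m e-folding; within the observed 0–19 and chosen so the UEZ-
  integrated fixation sits inside the observed 0.4–2.8 µmol N m^-2^ d^-1^
  band — a profile at the 19 tr L^-1^ extreme everywhere would integrate
  above the observed integrals); Beer–Lambert PAR (1500 µmol photons
  m^-2^ s^-1^, $k$ = 0.04 m^-1^); day tows with lognormal noise and known
  per-class migrant fractions.

Seeds are split per generator from the master seed by fixed documented
offsets, so each generator is a pure function of its configuration and
repeated calls are bit-identical.

What the generator does *not* emulate — and therefore what passing tests do
not show about real data: internal-wave strain and salinity spiking in CTD
profiles (overturns are clean reversals), ageostrophic and divergent
surface currents (so real conservation residuals will not be at rounding
error), ocean-colour retrieval bias (only unbiased noise and clouds),
vertical structure in POC, time-evolving eddies beyond uniform drift, and
zooplankton patchiness across tow pairs. The generator validates the
*machinery* (sorting, detection, discretisation, bookkeeping) and provides
realistic magnitudes; it cannot validate the geophysical assumptions.

## Numerical choices and degenerate inputs

* Stable sort with index-order tie-break: equal densities never count as
  inversions.
* Patch closure uses a cumulative-displacement tolerance of
  10^-9^ × max depth.
* Gradient fits fall back to the nearest bracketing samples when a layer
  contains fewer than two points, and error below two.
* Fluxes with negative $K_z$, empty flux series, polygons with fewer than
  three distinct vertices, non-overlapping profile spans, and budgets with
  missing terms all raise immediate, named errors.
* Longitudes on 0–360° are rewrapped to ±180°; descending axes are flipped
  with their data on read.
* The pipeline aborts with the failing stage's name.

Problem sizes in the shipped tests and acceptance script — 20–100 casts at
0.25-m resolution, ~90 × 60 tracer cells over ten composites, 1000
oracle-checked random profiles — were chosen as the smallest sizes at which
every property is exercised at full resolution; the whole suite and the
acceptance script each complete in well under a minute on one CPU.

## Known limitations

The lateral estimate inherits every assumption of the surface-flux method:
Redfield stoichiometry of the particles, vertical uniformity over the
upper 55 m, and currents representative of that layer. Thorpe analysis
resolves only overturns larger than the sampling interval and noise
threshold, and the $\Gamma$, $a$ constants carry order-of-factor-two
uncertainty. The eddy detector is single-snapshot and assumes closed SSH
contours survive gridding. Uncertainty propagation beyond min/max scenario
bounds (e.g., a Bayesian budget inversion) is out of scope, as are
dissolved organic and inorganic lateral pools, which require a
three-dimensional biogeochemical model rather than surface fields — though
`control_volume_flux()` applies unchanged to any tracer grid supplied.
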