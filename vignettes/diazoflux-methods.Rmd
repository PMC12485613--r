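---
title: "From tracer incubations to basin-scale N2 fixation budgets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From tracer incubations to basin-scale N2 fixation budgets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diazoflux)
```

## The problem

Marine dinitrogen (N2) fixation by diazotrophic cyanobacteria supplies
new nitrogen to the oligotrophic ocean, but both rates and diazotroph
abundances are measured at a sparse set of stations. Extending those
observations to basin scale requires a chain of quantitative steps, each
with its own conventions and failure modes:

1. converting shipboard 15N2 tracer incubations into volumetric and
   depth-integrated fixation rates, with defensible detection limits;
2. converting qPCR threshold cycles into absolute *nifH* gene copy
   concentrations per phylotype;
3. describing each phylotype's ecological niche as a smooth function of
   environmental covariates;
4. projecting those niches onto gridded climatologies, classifying which
   taxon dominates where; and
5. multiplying regional mean areal rates by region areas to obtain
   nitrogen fluxes in Tg N yr^-1^.

`diazoflux` implements this chain for the unicellular cyanobacterium
UCYN-B (*Crocosphaera*-like) and its co-occurring phylotypes
(*Trichodesmium*, UCYN-A, *Richelia*), together with a synthetic-data
generator that produces every input with known ground truth, so each
stage can be validated end to end without any external download.

## Rate calculation and detection limits

The volumetric rate for one incubation bottle follows the standard
isotope mass balance for the 15N2 dissolution method:

$$\rho = \frac{A_{PN}(t) - A_{PN}(0)}{A_{N_2} - A_{PN}(0)}
  \cdot \frac{[PN]}{\Delta t} \times 1000
  \quad [\mathrm{nmol\,N\,L^{-1}\,d^{-1}}]$$

where $A$ are 15N atom% values, $[PN]$ is the particulate-nitrogen
concentration in µmol N L^-1^ and $\Delta t$ the incubation length in
days. Default labelling values are 1.41 atom% for bulk and 1.56 atom%
for <10 µm incubations, with standard deviations 0.083 and 0.077 atom%
— the observed variability of membrane-inlet mass-spectrometric
measurements of the dissolved pool.

Two detection limits are attached to every rate:

* **LOD-1** substitutes the minimal atom% difference the IRMS can
  resolve ($^{min}\Delta A_{PN}$, default 0.00146 atom%; the function
  `min_delta_apn()` computes the 3-sigma value from replicate standards,
  e.g. `min_delta_apn(0.00017)` = 0.0005 at one significant figure)
  into the rate equation.
* **LOD-2** propagates the variability between duplicate bottles. The
  exact propagation recipe is not standardised; this package uses a
  first-order delta method over the final PN atom%, the PN concentration
  (both as duplicate spreads) and the N2-pool atom% (fixed SD), and sets
  LOD-2 = 3 × propagated SD to mirror LOD-1's 3-sigma convention. The
  multiplier is an argument. The delta method is checked against a
  10^5^-draw Monte-Carlo oracle in the test suite and agrees within 5%
  for coefficient-of-variation ≤ 10% inputs.

Negative enrichment (final atom% below initial, possible through noise
at near-zero rates) is clipped to zero and flagged; negative rates never
enter depth integrals. Depth integration is trapezoidal, with the
shallowest measured value extended unchanged to the surface and the
integral truncated at the deepest sampled depth (the 0.1% light level).
Those edge rules are a package choice — field reports rarely state
theirs — and both are deliberately conservative: no extrapolation below
the sampled layer.

## qPCR quantification

Standard curves are ordinary least squares of mean Ct on log10 copies
per well over a dilution series (10^0^–10^6^ copies per well by
default); efficiency is $(10^{-1/slope}-1)\times 100\%$. Unknowns are
inverted through the curve and converted to copies L^-1^ with an
explicit scaling factor (elution volume / template volume) and the
filtered volume — there is intentionally no hidden default for the
scaling, because it differs between extraction protocols. Flags use 25
copies L^-1^ (detection) and 250 copies L^-1^ (quantification);
non-amplified wells are dropped, at least two amplified wells are
required for an unflagged result, and an all-negative triplicate reports
0 copies L^-1^ flagged `<LOD`. In depth integration, `<LOD` values enter
as zero and `<LOQ` values at face value; both substitutions are
arguments.

## The niche model

`niche_gam()` fits, per taxon,

$$\log_{10} N_{nifH} \sim s(SST) + s(dFe) + s(P)$$

a Gaussian additive model with one univariate penalized cubic regression
spline per covariate (basis dimension 6 by default), smoothing
parameters selected by REML (GCV available). SST is sea-surface
temperature in °C, dFe dissolved iron in nM, P phosphate in µM; the
response is depth-integrated *nifH* abundance in copies m^-2^.
Design choices worth knowing:

* **Zeros.** log10 of a non-detect is undefined. The default drops
  zero-abundance records before fitting; flooring them at a
  detection-limit abundance is available (`zero_handling = "floor"`).
  With real compilations this choice changes the effective *n* and
  should be reported alongside any fit.
* **Extrapolation.** Predictions clamp covariates to the training hull
  and flag the cells. Penalized splines extrapolate linearly at best and
  wildly at worst; clamping makes global projection safe at the cost of
  flattening responses beyond the data.
* **Basis size.** k = 6 per term is enough for the broad unimodal or
  saturating responses expected of these taxa, and deliberately small to
  resist overfitting sparse compilations. The test suite shows a k = 6
  fit recovers a prescribed bump/saturation/peak truth with partial
  response RMSE ≤ 0.3 log units (n = 600, noise SD 0.5); exact
  interpolation of a noiseless truth requires the truth to lie in the
  spline span, which the recovery tests exercise with linear responses.
* **Uncertainty.** Partial-response bands are 95% intervals from the
  Bayesian posterior covariance of the spline coefficients, as is
  conventional for penalized regression.

Fitted models serialize to a portable JSON format (`write_niche_gam()`)
holding the covariate hull, the constant, and each smooth as a dense
piecewise-linear curve (512 points by default). This reproduces
predictions to interpolation error — far below the fit's own uncertainty
— without requiring the fitting machinery downstream; it does not
attempt to round-trip the spline basis itself, whose constraint
reparameterization is training-data dependent.

## Projection, dominance and hotspots

`project_taxon()` evaluates a fitted niche on monthly 1°×1° fields of
SST, dFe and P, back-transforms to copies m^-2^, and annualizes by
averaging the twelve monthly abundances in linear space (abundance, not
its log, is the budgeted quantity; geometric averaging is an option).
`dominance()` assigns a cell to a taxon iff its share of the summed
abundance strictly exceeds 75% *and* the summed abundance strictly
exceeds a floor. Two floors are kept as named presets, reflecting their
different purposes: 10^4^ copies m^-2^ for dominance cartography and
10^8^ copies m^-2^ for delineating high-fixation hotspot regions. The
package preserves both rather than resolving the order-of-magnitude gap
between them.

`hotspot_regions()` labels connected components of qualifying cells
(8-connectivity, wrapping across the antimeridian but not over the
poles) and reports areas from spherical cell weights
$A = R^2 \Delta\lambda (\sin\phi_2 - \sin\phi_1)$ with R = 6371 km —
budget-level accuracy; the global cell-area sum reproduces $4\pi R^2$
to well under 0.01%.

## Flux budgets

`regional_mean_rates()` computes arithmetic and geometric means of areal
rates, optionally excluding methods that bias low (the 15N2 bubble
method and acetylene reduction). Zeros are excluded from the geometric
mean only, and counted. `flux_tg_per_year()` converts a mean areal rate
and an area:

$$F = \rho \,[\mu\mathrm{mol\,N\,m^{-2}\,d^{-1}}] \times 14.007
  \times 365 \times A\,[10^6\,\mathrm{km^2}] \times 10^{-6}
  \quad [\mathrm{Tg\,N\,yr^{-1}}]$$

using 14.007 g mol^-1^ and a 365-day year (these constants reproduce
published budget arithmetic exactly; 1 µmol N m^-2^ d^-1^ over
10^6^ km^2^ is 0.005113 Tg N yr^-1^). `budget_table()` applies one rate
pair across a region set and keeps totals exact before rounding; its
print method rounds to one decimal in Tg.

```{r budget}
regions <- data.frame(
  name = c("Western North Pacific", "South Pacific", "Indian Ocean",
           "South Atlantic"),
  area = c(7.18, 2.20, 5.10, 0.45),
  comparison_geometric = c(4.3, 2.1, 0.3, 0.1),
  comparison_arithmetic = c(4.7, 2.4, 0.3, 0.1))
budget_table(regions, rate_geometric = 142, rate_arithmetic = 197)
```

`ucynb_contribution()` estimates the share of bulk fixation attributable
to UCYN-B from its areal *nifH* abundance, the per-cell gene polyploidy,
and a nanoSIMS cell-specific rate. The 95% interval uses Monte-Carlo
propagation of lognormal input uncertainty (10^5^ seeded draws) rather
than a delta method, because the ratio of skewed inputs is itself
skewed; the fraction may legitimately exceed 100% and is not clipped.
The polyploidy and cell-rate values are required user inputs — they come
from specialised measurements, not from this pipeline.

## What the synthetic generator emulates — and what it does not

`sim_config()` fixes a seed and the study conditions: stations sampled
at six light levels (100/50/25/10/1/0.1% surface PAR) with duplicate
bulk bottles over 24 h; qPCR standards 10^0^–10^6^ copies per well in
triplicate with 0.1-cycle replicate noise; a 600-record global niche
database over SST 10–31 °C, dFe 0.01–1.2 nM, P 0.01–1.5 µM with
lognormal abundance noise (0.5 log10 units); monthly 1° climatologies
with smooth latitudinal structure, a seasonally migrating thermal
equator and rectangular synthetic continents.

Noise models are the simplest consistent with the fitted forms: Gaussian
on atom% and Ct, Gaussian on log10 abundance. The bundled UCYN-B-like
truth (`ucynb_truth()`) has a Gaussian temperature optimum at 27.5 °C, a
saturating iron response with half-saturation at 0.2 nM and a phosphate
peak at 0.1 µM — the qualitative niche shape reported for warm-water
unicellular diazotrophs. Hidden truth travels in a separate `truth`
element, never in the analysis-facing tables.

The generator does **not** emulate spatial autocorrelation of stations,
covariate error, method-dependent rate bias, realistic coastlines or
ocean circulation, or sequencing data. Passing the recovery tests
therefore demonstrates that the estimators are correct and well
calibrated under idealized sampling — not that a real-world compilation
meets those assumptions. In particular, real databases mix measurement
methods and cluster along cruise tracks, so real-data fit statistics
should be expected to be worse than the synthetic ones.

## Numerical choices and degenerate inputs

* Trapezoid integration is exact for piecewise-linear profiles; profiles
  need ≥ 2 distinct depths.
* Tracer inputs with $A_{N_2} \le A_{PN}(0)$ are an error (the tracer is
  undefined), not a zero.
* Shares of an all-zero community are all-`NA` with an `undefined`
  attribute, not zeros.
* Dominance ties at exactly the threshold go to `"none"` (strict
  inequality).
* An empty hotspot set is an empty table, not an error.
* Problem sizes in the test suite (600-record databases, 20-seed
  recovery, 10^5^ Monte-Carlo draws, 5×5 dominance grids × 1000 trials)
  were chosen so the full validation runs in well under a minute on one
  core while keeping Monte-Carlo error comfortably inside the asserted
  tolerances.

## Known limitations

* The niche trio (SST, dFe, P) is fixed; no covariate selection or
  interaction smooths are offered.
* Clamped extrapolation means projected abundances outside the training
  hull are boundary values — flat, not declining. Interpret flagged
  cells accordingly.
* Areas use a spherical Earth; the error relative to an ellipsoid is
  ~0.1–0.3%, negligible against rate uncertainty.
* The conversion from gene copies to cells divides by a single average
  polyploidy value; real polyploidy varies with cell cycle and
  environment.
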