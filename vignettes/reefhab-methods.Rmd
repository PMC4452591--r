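---
title: "Diagnostic modelling of potential coral-reef habitat: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnostic modelling of potential coral-reef habitat: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reefhab)
```

## The model

Tropical reef-building corals persist only inside a bounded envelope of
environmental conditions. `reefhab` implements a diagnostic
threshold-envelope model of potential reef habitat on nested equal-angle
grids. A 30-arcsecond cell is classified as potential reef habitat when two
conditions hold:

1. **Environmental envelope (1°)**. The enclosing one-degree cell satisfies,
   inclusively,
   $T_{\min} \le T \le T_{\max}$, $S_{\min} \le S \le S_{\max}$,
   $[\mathrm{NO_3^-}] \le \mathrm{NO_3^{max}}$,
   $[\mathrm{PO_4^{3-}}] \le \mathrm{PO_4^{max}}$ and
   $\Omega_{ara} \ge \Omega_{\min}$.
2. **Light at depth (5′ + 30″)**. The cell's depth $Z$ (positive downward, m)
   satisfies $0 < Z \le Z_{\max}$, where the maximum depth of reef growth is
   computed from the enclosing 5-arcminute light fields:
   $$Z_{\max} = \frac{1}{K_{490}}\,\ln\!\frac{\mathrm{PAR}}{I_{\min}},
   \qquad \mathrm{PAR} > I_{\min},$$
   and $Z_{\max} = 0$ otherwise.

The light relation is the Beer–Lambert attenuation of surface PAR written
with depth positive downward; the equivalent form
$\ln(I_{\min}/\mathrm{PAR})/K_{490}$ differs only in sign convention. We use
the positive-depth form so that the depth test reads $0 < Z \le Z_{\max}$,
and we make the comparison inclusive: ties are measure-zero on real data,
and inclusivity keeps the corner case $\mathrm{PAR} = I_{\min}$, $Z = 0$
consistent with "no suitable depth". Cells with $Z \le 0$ (land or
intertidal in the bathymetry) are never habitat.

Suitability decided at 30″ is summarised at 1° as the fraction of positively
evaluated 30″ cells in each 1° cell (`aggregate_fraction()`). The
denominator is the *full* 120 × 120 block, land and ocean alike; the same
convention is applied to observed reefs, so predicted and observed fractions
are directly comparable.

### Grids, areas and missing data

Grids are cell-centered with half-open cells $[\mathrm{lo}, \mathrm{hi})$ on
both axes, so every point belongs to exactly one cell and rasterization is
deterministic. The three canonical resolutions nest exactly: one 5′ cell
contains 100 cells of 30″, one 1° cell contains 14 400. Inputs that do not
nest are rejected rather than resampled.

Cell areas use the exact spherical-zone formula on a sphere of radius
$R = 6371$ km: $A = R^2\,\Delta\lambda\,(\sin\varphi_{hi} -
\sin\varphi_{lo})$. Summed over any grid this closes on the analytic band
area to near machine precision (asserted at $10^{-12}$ relative in the test
suite), and total habitat area computed by summing suitable 30″ cells agrees
with the alternative route (1° fraction × 1° cell area) to well within 0.1%.

Missing data are treated conservatively where the variable is load-bearing
and permissively where real archives force gaps:
missing temperature, salinity or nutrients make a 1° cell unsuitable;
missing $\Omega_{ara}$ (or a cell inside the configured region mask - the
gridded carbon climatology has no alkalinity/DIC in the Indonesian Sea and
the Caribbean) skips only the saturation-state check; missing PAR or
$K_{490}$ fails the light criterion for the affected block. The region mask
ships as configurable rectangles (`default_omega_mask()`: Indonesian Sea
lat −12..8, lon 94..141; Caribbean lat 8..28, lon −90..−58) because no
authoritative coordinates exist for these data gaps.

`lookup_coarse()` additionally provides a nearest-neighbour fill within a
one-cell radius (edge-adjacent neighbours before diagonal, fixed tie order)
for workflows that need a value for every fine cell near coastlines; the
habitat decision itself uses only the enclosing cell.

## The carbonate-system solver

$\Omega_{ara}$ is not observed directly; it is computed from total
alkalinity (TA) and dissolved inorganic carbon (DIC) at the local
temperature and salinity. `solve_carbonate_system()` finds the hydrogen-ion
concentration at which the modelled alkalinity equals the input TA for the
given DIC, on the total pH scale at surface pressure.

Constants are the conventional open-ocean surface set: $K_1, K_2$ from
Lueker et al. (2000), boric acid from Dickson (1990), water from Millero
(1995; seawater scale, converted to total), aragonite/calcite solubility
from Mucci (1983), total boron from salinity (Uppström 1974) and calcium
proportional to salinity (Riley & Tongudai). The alkalinity model is
restricted to the carbonate, borate and water terms; nutrient and
minor-acid contributions are neglected. At surface-ocean nutrient levels
this approximation moves $\Omega_{ara}$ by far less than the 0.01 agreement
bound asserted against an independently implemented reference solver (108
combinations spanning $T \in [15, 30]$ °C, $S \in [30, 40]$,
TA $\in [2100, 2500]$, DIC $\in [1800, 2200]$ µmol kg⁻¹, frozen in
`tests/testthat/omega-reference.csv`).

The root finder is a bracketed bisection on pH $\in [2, 12]$ (geometric
bisection in H) refined by Newton steps safeguarded back into the bracket,
to a relative tolerance of $10^{-10}$ in H. Because modelled alkalinity is
continuous and strictly decreasing in H, with the water term diverging at
the alkaline end, a unique root exists for any positive TA/DIC; the solver
still verifies the bracket and reports the offending inputs if it is ever
lost. Self-consistency (re-evaluating alkalinity at the returned state
reproduces the input TA to $10^{-10}$ relative) is asserted over 1000 random
inputs.

## Inverse mode: tolerance limits from observed reefs

Observed reef polygons are rasterized by **vertex membership**: every 30″
cell containing at least one polygon vertex is marked as observed reef.
Interiors are deliberately not filled - charted reef areas are recorded as
vertex polygons, and filling would change the observed area; this is a
fidelity choice, not a simplification. A 1° cell is a *reef cell* when its
observed fraction is above 0, the same presence definition used in
evaluation.

`derive_limits()` then takes the global extremes of each variable over reef
cells: two-sided ranges for temperature and salinity, upper thresholds for
the nutrients, a lower threshold for $\Omega_{ara}$ (excluding masked or
missing cells). Raw extremes are used - no outlier trimming - so a single
extreme reef location (an upwelling region, a hypersaline sea) legitimately
sets the threshold; an off-by-default quantile trim is available for
sensitivity analysis only. With `time_scale = "monthly"` or `"weekly"` the
extremes are taken across all time slices, so annual ranges nest inside
monthly ranges, which nest inside weekly ranges.

$I_{\min}$ is deliberately **not** derived by inversion. Charted reef
positions are inconsistent with high-resolution bathymetry in places (reefs
recorded over kilometres-deep water), and inverting the light relation at
such cells yields unrealistically low irradiance thresholds. Instead
$I_{\min}$ is optimized against the observations.

## Evaluating predictions and optimizing the light threshold

Predicted and observed 1° presence matrices (1 where the fraction is above
0) are subtracted: observed − predicted is −1 at false positives, +1 at
false negatives and 0 at matches. From the counts,
$\mathrm{TPR} = \mathrm{TP}/(\mathrm{TP+FN})$ and
$\mathrm{FPR} = \mathrm{FP}/(\mathrm{FP+TN})$; model quality is the
Euclidean distance from $(\mathrm{FPR}, \mathrm{TPR})$ to the perfect
classification corner $(0, 1)$ of the ROC graph - the standard reading of
"distance to the perfect point". Cells with wholly missing environments
count as true negatives when neither map marks them.

`sweep_imin()` re-evaluates the model across candidate $I_{\min}$ values.
Only the light criterion depends on $I_{\min}$, so the envelope is computed
once; each fine cell's critical irradiance
$\mathrm{PAR}\,e^{-K_{490} Z}$ is precomputed, making every sweep point a
threshold comparison that is exactly equivalent to a full re-prediction
(asserted in the tests). Raising $I_{\min}$ only shrinks the suitable set,
so false positives are non-increasing and false negatives non-decreasing
along any sweep. The default protocol scans 50-500 in steps of 50, then
refines at step 10 across the interval bracketing the coarse optimum. Ties
in distance resolve to the smaller $I_{\min}$ (the less restrictive
habitat).

## The synthetic-world generator

Real inputs to this analysis are global archives (hydrographic
climatologies, a gridded carbon climatology, ocean-colour light fields,
global bathymetry, charted reef polygons). The generator replaces them with
a co-registered multi-resolution world whose ground truth is known exactly,
so every stage of the pipeline is testable offline:

- **Coarse fields (1°)**: temperature with a latitudinal gradient plus
  smooth low-order harmonic noise, spanning beyond both planted temperature
  bounds; salinity with a fresh plume and a hypersaline pool crossing both
  salinity bounds; nutrients with an upwelling corner exceeding both
  thresholds; TA/DIC with a corrosive region driving $\Omega_{ara}$ below
  its bound. Harmonic mixing keeps the fields smooth and fully determined
  by the seed.
- **Light (5′)**: PAR decreasing with latitude; $K_{490}$ elevated towards
  the coast.
- **Bathymetry (30″)**: a land strip, a shelf ramp (≈3-58 m), a slope and
  abyssal cells with harmonic relief.
- **Planted structure**: each tolerance bound is inserted *exactly* at one
  designated reef cell (the $\Omega_{ara}$ bound by solving DIC at one cell;
  the realized value is recorded in the truth), so inverse-mode recovery is
  exact rather than distribution-tail luck. A ladder of single-pixel
  shallow sites with critical irradiances spaced through the sweep range
  makes false positives decay stepwise up to the planted $I_{\min}$, and a
  few marginal reef sites just above it make false negatives jump
  immediately beyond - so the ROC sweep recovers the planted optimum to
  within one refinement step.
- **Imperfection**: `omission_rate` leaves suitable cells reef-free
  (persistent false positives, emulating uncharted reefs);
  `commission_rate` drops reef polygons over abyssal water (irreducible
  light-only false negatives, emulating the depth/reef mismatches of
  charted data). Commission cells keep envelope-interior water properties,
  so they perturb only the light criterion, as intended.

The default world spans 10° × 20° (200 coarse cells, 28 800 5′ cells,
2.88 million 30″ cells), sized so the full pipeline - generation, inverse
mode, coarse-plus-refined sweep - completes in well under a minute on one
CPU. Identical seeds give bit-identical worlds.

**What passing tests do and do not show.** Exact limit recovery and
$I_{\min}$ recovery on these worlds validate the *machinery*: rasterization,
nesting, aggregation, the decision flow, the confusion/ROC accounting and
the sweep protocol. They do not validate the ecological realism of any
particular tolerance value on real archives: synthetic fields have no
ocean-circulation structure, no data gaps beyond the constructed ones, no
coastline geometry, and reef placement follows the model's own suitability
rule. Conclusions about real oceans require the real inputs, which the
pipeline accepts through the same netCDF/CSV interfaces.

## Numerical choices and degenerate inputs

- Spherical Earth, $R = 6371$ km; no projection, no curvilinear grids.
- Longitudes are normalized to $[-180, 180)$ on read; files on $[0, 360)$
  are rotated column-wise.
- Nesting checks use a $10^{-6}$-degree tolerance on exact divisibility;
  non-nesting grids are errors, never resampled.
- The carbonate solver tolerance is $10^{-10}$ relative in H; the
  DIC-planting solve in the generator nudges DIC (in $10^{-6}$ µmol kg⁻¹
  steps) so the realized $\Omega_{ara}$ sits at or above the planted bound
  under the inclusive envelope check.
- Empty reef sets, all-missing variables over reef cells, degenerate
  confusion worlds (no positives or no negatives) and reversed latitude
  bounds raise informative errors rather than returning silent defaults.

## Known limitations

- The alkalinity model omits nutrient terms; at high-nutrient settings the
  $\Omega_{ara}$ bias grows beyond the surface-ocean regime it is tuned for.
- Pressure is fixed at 0 dbar; the solver is not meant for subsurface work.
- Vertex rasterization undercounts reef area relative to polygon interiors;
  this mirrors the charted-data convention but both predicted and observed
  areas inherit it.
- Evaluation is presence/absence at 1°; fraction-weighted skill scores, AUC
  and alternative skill statistics are out of scope.
- The time-resolved inverse mode assumes time slices on the same 1° grid as
  the annual fields.
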