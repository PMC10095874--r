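---
title: "Methods: compiling ecosystem natural capital accounts with encar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: compiling ecosystem natural capital accounts with encar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(encar)
```

`encar` compiles biophysical ecosystem accounts for a river-basin
territory: stocks, flows, accessible resources, uses and condition indices
for land cover, water, bio-carbon and ecosystem infrastructure, integrated
per socio-ecological landscape unit (SELU) into a total-ecosystem-
capability indicator. This vignette is the package's own account of the
method: the statistical units, the four accounts and their index formulas,
the synthetic-watershed generator that provides the test conditions, and
the numerical and design conventions the implementation adopts.

## Statistical units

The accounting frame has three layers, all pixel-registered on one grid of
nominal 1-ha cells in a single projected CRS (the package never
reprojects or resamples; misaligned layers are an error):

* **DLCT** — dominant land-cover types, a 10-class aggregation of a
  detailed source nomenclature. The aggregation table is configuration; a
  CORINE-style 44-to-10 default ships in
  `inst/extdata/clc44_to_dlct10.yaml`. Reclassification is a pure
  relabelling, so non-nodata area is conserved exactly.
* **ENCAT / UZHYD** — accounting catchments and their elementary
  hydrological zones, carried as a label raster plus a downstream relation
  (required acyclic) between UZHYDs.
* **SELU** — one per UZHYD, labelled with the zone's dominant DLCT at the
  opening epoch. The dominant class is the one of maximal area; ties break
  to the lowest class code so the result is deterministic and independent
  of cell order. Labelling at the opening epoch keeps the statistical
  units fixed across epochs, which is what makes stocks and flows
  comparable; the alternative reading — subdividing a catchment into one
  unit per contiguous DLCT patch — would re-delineate units whenever land
  cover changes and break the time series, so it was rejected. The SELU
  set partitions the accounted territory by construction, and
  `validate_selus()` asserts it.

Nodata cells are excluded from every area tabulation; a zone more than
half nodata triggers a warning and a zone with no data at all is an error
rather than a silent gap.

## The four accounts

### Land cover

The transition matrix between epochs cross-tabulates aligned rasters:
entry $(i, j)$ is the area moving from class $i$ to class $j$. Row sums
are opening stocks, column sums closing stocks, and the per-class balance

$$\text{closing}_i = \text{opening}_i + F_i - C_i$$

with consumption $C_i$ (off-diagonal row sum) and formation $F_i$
(off-diagonal column sum) holds exactly in integer pixel counts. Flows are
recorded gross — both directions of a class pair — and net values are
derived, never stored. Drivers of change are assigned by an ordered
first-match rule table over $(i, j)$ pairs; the shipped default
distinguishes artificialisation, agriculture internal conversion and
extension, forest & shrub translation, glacier retreat, water-body &
wetland change, and an explicit "other changes n.e.s." catch-all, and is
deliberately approximate — the taxonomy is configuration, not doctrine.
Multi-period accounts chain by summing gross flows, keeping the first
opening and last closing stock, after checking the junction stocks match.
Reported percentage changes are relative to the opening stock and, when
whole percents are requested, rounded half away from zero (`round()`'s
half-to-even would turn a 10.65% change into 10%, not the conventionally
reported 11%).

### Water

Each UZHYD carries an annual balance in hm³/yr. Units are evaluated in
topological order of the downstream relation; the upstream inflow of a
unit is the summed runoff of its immediate upstream neighbours. Local
runoff is $\max(0, P + Q_{in} - ET - A)$; a deficit is drawn from storage,
so the closure identity holds to machine precision for every unit and the
sum of local runoffs equals the outlet inflow on tree topologies (both are
asserted in tests). The accessible surplus is

$$S = \varphi \cdot \max(0,\; P + Q_{in} - ET),$$

where the exploitable fraction $\varphi \in [0,1]$ (default 0.5) reflects
restrictions of use; the formula itself is the package's choice — the
accessible-resource concept does not fix an expression. The intensity
index divides $S$ by **net consumption** (withdrawals − returns) rather
than gross withdrawal, because return flows are available again
downstream; zero consumption yields an `Inf` sentinel that the
integration layer caps to 1 ("no depletion"). Groundwater is carried as a
dimensionless level index, never as a volume in the balance. The account
uses an annual step; intra-annual seasonality is out of scope.

Rivers are weighted in standard river kilometres, $SRKM = \text{length}
\times \text{discharge}$ (the normalisation constant is a configurable
scale, default 1), which makes reaches of different size additive — SRKM
is exactly additive under splitting a reach. Reaches are classed
small/medium/large by two strictly increasing discharge cut-offs with
half-open intervals, the boundary assigned upward. Status-change shares
(degraded / improved / stable between epochs, from ordinal classes 1 =
high … 5 = bad) are SRKM-weighted.

### Bio-carbon

The accessible resource is net ecosystem production, $NEP = NPP - R_h$.
Negative NEP is reported raw for diagnostics but contributes zero
accessible resource — an explicit floor, so that a carbon-source SELU
shows maximal use intensity rather than a negative index. Use totals
crops harvest, wood removals and animal withdrawals (livestock converted
via a configurable tC/head/yr coefficient, default 0.15); stock
conversions use volume × wood density × expansion factor × carbon
fraction with the conventional carbon fraction 0.5. Soil carbon is a
stock only and never enters the flow account. The index is
$NEP_{acc}/use$; its reciprocal, the use fraction, is reported in percent
and the identity $index \times fraction = 1$ is asserted over random
draws.

### Ecosystem infrastructure

The landscape potential multiplies three 0–1 indices per SELU:

* **greenness** — area-weighted mean of per-class green weights (a
  configurable stand-in for a vegetation index; weights ship with the
  default scheme);
* **fragmentation** — the effective-mesh ratio $\sum_i A_i^2 /
  A_{tot}^2$ over 4-connected green patches after cutting barrier cells
  (roads, sealed surfaces). $A_{tot}$ is the green (non-barrier) area of
  the SELU, not its total area: with that convention a single connected
  patch scores exactly 1 and $n$ equal patches $1/n$, making the index a
  pure fragmentation measure — the green *share* already enters NLEP
  through the greenness factor, and using total SELU area would double-
  count it. An all-barrier SELU scores 0 with a warning;
* **nature value** — protected/high-nature-value area share mapped
  through a two-point weight table (defaults 0.5 outside, 1 inside).

$NLEP = g \times f \times nv$; the quantity form multiplies by SELU area.
$NREP$ multiplies river condition potential (ordinal status via the
lookup 1→1.0, 2→0.8, 3→0.6, 4→0.4, 5→0.2, configurable) by the
conservation-value index, and its quantity is weighted by the SELU's SRKM
so that river and landscape potentials are commensurable and $TEIP =
NLEP_q + NREP_q$ is a meaningful sum — an implementation convention, not
a measurement claim. Intensity of use for the infrastructure account is
the yearly change of these quantities under the linear convention
$((v_1 - v_0)/v_0)/n$.

The health index is a weighted arithmetic mean (equal weights by default)
of water-quality, biodiversity-change and vulnerability components, each
in $[0,1]$; any degraded component with positive weight drags it below 1.
The combination rule is a package choice — only the components and their
range are fixed by the accounting framework.

## Integration into capability

Per SELU and account: the raw intensity index is capped at 1
($\min(r, 1)$; the zero-use sentinel maps to 1), averaged with the health
index into the account's ecological unit value (equal weights by default,
configurable), and the three unit values are summed:

$$TEC = UVW + UVC + UVEI \in [0, 3] \text{ ECU}.$$

The averaging rule is the one definition of the unit value the framework
states; the original per-account weighting is unknown, so equal weights
are the default and a parameter, not a constant. Missing inputs (e.g. no
health data for an account) withhold that unit value and flag TEC as
partial — nothing is imputed. For the capability layer the infrastructure
intensity is taken as $1 + $ yearly TEIP change, capped like the others,
so that a declining infrastructure reads as an intensity below 1 at the
closing epoch and the opening epoch is the baseline 1. Watershed summaries
are area-weighted means over SELUs; hotspots are SELUs whose capped index
is below 1 at the final epoch and declined by more than a threshold
(default 0.1), sorted by decline.

## The synthetic watershed

The generator provides complete, internally consistent input sets so the
whole chain is testable without any external data. One integer seed
drives everything through fixed per-layer sub-streams, so adding a layer
never changes another layer's draw. Its design:

* **Land cover** — classes are sliced from a smooth pseudo-elevation
  field (iterated 3×3 smoothing of white noise) by quantiles of the
  requested class mix, ordered water → wetland → arable → artificial →
  permanent crops → pasture → forest → shrub → bare → glacier. Realized
  fractions match the request exactly up to integer pixel counts, and the
  mosaic is spatially coherent. The default mix (forest 0.40, pasture
  0.28, arable 0.15, artificial 0.04, …) reflects a large temperate basin
  in which forests, pastures and arable land dominate.
* **Catchments** — a seeded Voronoi partition into UZHYDs; the downstream
  relation sends each unit to the neighbouring unit strictly closer to
  the outlet (the lowest-elevation seed), which is acyclic by
  construction. Reaches get one segment per UZHYD, length scaling with
  $\sqrt{area}$ and discharge accumulated downstream from a specific
  runoff of ~10 l/s/km².
* **Change** — exactly `round(rate × eligible cells)` cells per process
  are converted by seeded sampling: arable → artificial at 0.11, forest →
  transitional woodland at 0.02, glacier → bare at 0.13 per 12-year
  period. These defaults are the documented magnitudes of change for a
  large temperate watershed over 2000–2012 and are what the
  parameter-recovery tests check against.
* **Surfaces and uses** — precipitation and NPP are smooth positive
  fields (defaults 1000 ± 150 mm/yr and 6 ± 1.2 tC/ha/yr); actual ET and
  heterotrophic respiration are smooth 40–70% shares of them, so surplus
  and NEP are strictly positive everywhere. Sectoral use tables are
  calibrated so per-SELU net use equals `use_level ×` the accessible
  resource (defaults: water 0.1, carbon 0.35, the latter sitting in the
  30–40% range typical of exploited temperate basins), which makes the
  expected intensity indices analytically `min(1, 1/use_level)` — the
  round-trip identity the end-to-end tests assert.

What the generator does **not** emulate: realistic terrain or hydrography
(Voronoi cells are not drainage divides), seasonal climate, correlation
between land cover and productivity, classification error in the
land-cover product, or multi-reach river geometry within a zone. Passing
tests therefore demonstrate the correctness and internal consistency of
the accounting engine under known conditions — not the realism of any
particular territory's accounts.

## Numerical conventions and problem sizes

* All area arithmetic is exact in integer pixel counts; conservation
  checks use equality, not tolerances.
* Ratios use an `Inf` sentinel for zero denominators where the framework
  defines the limit (no use → no depletion → capped 1) and an error where
  it does not (negative inputs).
* Ties in dominance break to the lowest class code; first match wins in
  driver rules; patch labelling uses 4-connectivity.
* Whole-percent reporting rounds half away from zero.
* CSV outputs use a fixed column order, UTF-8, comma separator and full
  double precision, so identical runs are byte-identical — asserted by
  the determinism tests.
* The test suite runs the generator at 40–120 pixels a side with 4–12
  UZHYDs and the oracle comparisons on grids of 15–50 pixels a side;
  these sizes exercise every code path (multi-zone, multi-class,
  routed topology) while keeping the default suite fast. The engine
  itself is size-agnostic; memory scales with one integer matrix per
  epoch plus one distance matrix per Voronoi build.

## Known limitations

* No polygon geometry: zones are label rasters, so sliver-level geometric
  effects of vector overlays are outside the model. Interchange with GIS
  stacks goes through ESRI ASCII grid and CSV, both read natively by
  standard tools.
* Monetary valuation and restoration-cost estimation are out of scope;
  the output is biophysical capability in ECU.
* The water account has no process hydrology — ET and precipitation are
  inputs, not simulated; the engine is an accountant, not a hydrological
  model.
* Ecological status enters as pre-scored ordinal classes; the scoring
  methodology itself is not reproduced.
* With a single reach per UZHYD in the synthetic fixture, SRKM-weighted
  condition aggregation is exercised with one weight per zone; multi-reach
  weighting is covered by unit tests on constructed tables.
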