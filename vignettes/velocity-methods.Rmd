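---
title: "Class-binned climate-analog velocity for reserve networks: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Class-binned climate-analog velocity for reserve networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(topoclimvel)
```

## The problem

Protected-area (PA) networks are fixed in place while climate moves across
them. A widely used way to quantify this exposure is the *climate-analog
velocity*: for every grid cell, find the nearest location whose **future**
climate matches the cell's **present** climate, and divide that distance by
the number of years separating the two periods. Cells whose present climate
occurs nowhere in the future surface have a *disappearing climate*.

The velocity depends strongly on the resolution of the climate surfaces.
Terrain creates topoclimate — radiation loading on south slopes, cold-air
pooling in depressions, lapse-rate cooling with elevation — at scales of
tens to hundreds of metres. Fine-resolution surfaces therefore contain
nearby analogs (a cool hollow a few hundred metres away) that kilometre-
scale surfaces average away, so coarse data systematically overstate how
far climates must move. `topoclimvel` implements the full analysis needed
to quantify that effect for a reserve network, end-to-end, and ships a
synthetic landscape generator so every stage can be exercised and tested
without any external data.

## Bioclimatic variables

Three variables with established ecological meaning for high-latitude
systems are computed from monthly temperature normals and annual
precipitation (`gdd5()`, `t_jan()`, `wab()`):

* **GDD5** (growing degree days, °C·days): the annual effective temperature
  sum above a 5 °C base. From monthly normals it is estimated month-wise:
  months with mean temperature $T_m > 5$ contribute $(T_m - 5)\,d_m$ with
  $d_m$ the month length in a 365-day climatological calendar. The
  month-level threshold is applied to the temperature itself ($T_m > 5$),
  not to the excess over the base; the excess-over-base reading would make
  the stated 5 °C base meaningless.
* **T_Jan** (°C): the mean January temperature, a proxy for winter
  severity; simply the January grid.
* **WAB** (mm): the climatic water balance, annual precipitation minus
  potential evapotranspiration. PET uses the linear temperature-based
  formulation $PET = 58.93 \cdot \sum_m \max(T_m, 0) / 12$, i.e. 58.93
  times the annual mean of monthly temperatures clamped at 0 °C. The
  clamping is applied per month, before averaging, consistent with a
  monthly summation.

All three surfaces share one grid geometry and nodata mask; GDD is
non-negative by construction and both GDD and PET are monotone in every
monthly temperature (tested as properties).

## The velocity metric

`climate_velocity()` composes three steps, each exposed separately:

1. **`classify()`** — continuous surfaces are reclassified into fixed-width
   half-open bins, class $k$ covering $[k w, (k+1) w)$. Widths follow the
   established choices for these variables: 50 °C·days (GDD), 0.5 °C
   (T_Jan), 50 mm (WAB). The anchor is fixed at 0 in variable units, which
   makes class edges independent of the data and of the resolution track,
   so the fine and coarse analyses bin identically.
2. **`analog_distance()`** — for each present-day cell of class $c$, the
   Euclidean distance (cell centre to cell centre) to the nearest cell
   whose future class is $c$; 0 where the cell's own future class already
   matches. The search runs one exact Euclidean distance transform of the
   future label raster per present class (`EBImage::distmap`); a
   brute-force all-pairs search serves as the independent correctness
   oracle in the test suite. When a class is absent from the entire future
   surface the cell is flagged *disappeared* (an explicit flag, never a
   large sentinel number, so downstream statistics stay well defined).
   Ties between equidistant analogs are irrelevant because only the
   distance is kept. Nodata cells participate neither as origins nor as
   targets.
3. **`velocity_from_distance()`** — km/yr, dividing by 1000 and by the
   period separation. The default 89 years is the midpoint separation of a
   1981–2010 baseline and a 2070–2099 projection window; it is
   configurable.

Velocity is computed *forward* (present cell seeks its future analog).
On a clean linear gradient $g$ (variable units per metre) under uniform
warming $\Delta$, the metric must return $\Delta / (1000\,g\,\mathrm{yr})$
km/yr up to one bin-width-equivalent — this closed form anchors the
acceptance tests.

## Scenarios and the two resolution tracks

Future climates are built by adding coarse change fields ("deltas") to the
baseline normals (`apply_deltas()`): each monthly temperature delta and the
annual precipitation delta is bilinearly resampled onto the working
geometry and added (precipitation additively, in mm). Bioclimatic variables
are then **recomputed from the adjusted normals** (`build_scenario()`) —
never delta-adjusted directly, because GDD and PET are nonlinear in
temperature. Bilinear interpolation reproduces constants and planes
exactly, clamps to the nearest coarse centre beyond the outermost centres
(so a coarse delta field still covers fine border cells), and renormalises
weights around nodata neighbours.

The coarse track is produced by areal-mean aggregation
(`aggregate_mean()`, factor 20 for a 50 m → 1 km comparison) of the
monthly normals, after which the same deltas are resampled to the coarse
geometry and the variables recomputed. Both tracks therefore use identical
coarse change information and differ only in the resolution of the
baseline climate — the quantity whose effect the comparison isolates.

## Reserve-level exposure

`zonal_mean()` averages velocities over each reserve's cells (cell-centre
membership), excluding disappeared cells and reporting their fraction
separately; a reserve that has lost its entire climate is excluded from
rankings and flagged. For a reserve smaller than one coarse cell, where no
cell centre falls inside, membership falls back to the **single cell
containing the reserve's centroid**. Spreading a sub-cell reserve over
every cell its outline touches would attribute to it the climate variation
of up to four square kilometres of surrounding terrain; with the
centroid-cell rule the coarse within-reserve range stays nested inside the
fine range, which is the property the aggregation analysis relies on.

Hotspots are the top 5 % of reserves by mean velocity
(`top_fraction()`, floor(0.05 N), ties broken by reserve id for
determinism — in a 5,068-reserve network that is exactly 253 sites), and
`hotspot_overlap()` reports their cross-variable intersection as
$100\,|A \cap B| / |A|$ with $A$ the first-named variable.

Fine-vs-coarse comparisons use GDD only (WAB velocities are localised and
complex; T_Jan suffers wholesale climate disappearance under strong
warming, which would confound the comparison): a paired t-test on
per-reserve differences (`paired_velocity_test()`; the closed form
$\bar d / (s_d/\sqrt n)$, with a degenerate-variance flag instead of an
error when all differences are equal), and the symmetric relative
difference $RD = (c - f) / ((c+f)/2)$, bounded in $(-2, 2)$ and positive
where the coarse velocity is larger. The symmetric form is preferred over
$(c-f)/f$, which explodes as the fine velocity approaches zero; pairs with
both velocities zero are undefined and dropped with a warning.

`glm_relative_diff()` fits a Gaussian identity-link GLM of RD on relief
region (ordinal 1–3 coded as one linear term — the most parsimonious
ordinal treatment), log reserve area (hectares, natural log), log
within-reserve elevation range, and scenario as a factor. Effect sizes are
prediction ranges: response at the predictor's observed maximum minus at
its minimum, other predictors fixed at their means — which for the
identity link equals |coefficient| × range exactly (asserted analytically
in the tests), with the slope sign recorded separately.

## Range overlap and gaps

`pa_range_overlap()` compares each reserve's present [min, max] of a
variable with its projected future interval, per track. Intervals are
plain min–max ranges over the reserve's cells (not quantiles). Touching
intervals count as overlapping with gap 0 — the boundary case has to be
decided somehow and counting a shared boundary value as an analog is the
conservative choice. Disjoint intervals carry a gap size and a direction
(`future_above` for warming/wetting, `future_below` for drying, the WAB
signature). Because areal means can only pull within-reserve extremes
inwards, the coarse interval nests inside the fine interval for interior
reserves, so fine-track overlap counts dominate coarse-track counts and
fine gaps are never larger — the direction of effect the package's
acceptance checks assert on every synthetic run.

## The synthetic landscape generator

The generator is first-class, tested code; its defaults define the study
conditions used throughout the tests and the acceptance script.

* **`make_dem()`** — Gaussian-filtered white noise (correlation length
  1.5 km) rescaled so the height range inside 10-km blocks matches the
  relief class: flatlands < 50 m (default 35 m), undulating 50–200 m
  (default 120 m), rugged > 200 m (default 400 m) — the conventional
  three-way relief division. The field is scaled so the geometric midpoint
  of the extreme block ranges equals the target, keeping every block
  within ±20 %. An optional west–east elevation ramp (default 800 m for
  rugged landscapes) widens the domain's total climate span.
* **`make_monthly_climate()`** — additive topoclimate terms on the DEM: a
  boreal sea-level annual cycle (−8 … 16 °C), lapse rate −0.0065 °C/m, a
  south–north gradient, a southness radiation term (0.8 °C per unit
  index), winter-weighted cold-air pooling (weight 1 Dec–Feb, 0 Jun–Aug,
  linear between; 0.015 °C per metre of negative relative elevation, i.e.
  a 40-m hollow is 0.6 °C colder in January), and Gaussian noise
  (0.1 °C). Precipitation is 600 mm plus 0.5 mm per metre of elevation
  (orographic) plus noise. Cold-air pooling deliberately peaks in winter,
  reflecting that terrain decoupling of minimum temperatures is strongest
  under winter inversions, so the fine–coarse contrast is largest for
  T_Jan.
* **Scale compression.** A desk-scale domain (20 km) cannot contain a
  late-century warming signal's analogs if its climate span is only what
  20 km of real terrain provides; in the real analysis that role is played
  by a ~1000-km national macrogradient. The generator therefore compresses
  the macrogradient: the default meridional gradient is −0.3 °C/km
  (≈ −6 °C per 1000 km scaled into the domain) and rugged DEMs carry the
  regional ramp. These are scaled-down stand-ins chosen once, not observed
  local gradients, and the absolute analog distances they produce are
  correspondingly compressed; only directions of effect and internal
  consistency — not the field study's printed kilometre figures — are
  meaningful at this scale.
* **`make_delta_fields()`** — smooth 5-km fields with stated mean warming
  per pathway (defaults 1.5, 2.6, 4.6 °C for RCP2.6/4.5/8.5 — typical
  late-century high-latitude ensemble means), +40 mm precipitation, and a
  small correlated perturbation (0.05 °C).
* **`make_pa_polygons()`** — jittered-radius 14-gons rescaled to exact
  log-uniform areas (2–100 ha; 2 ha is the conventional minimum reserve
  size), placed disjointly and fully inside the domain, deterministic per
  seed.

Everything is deterministic for a fixed seed (`.Random.seed` is restored
afterwards, so generators do not clobber the caller's RNG stream).

What the generator does **not** emulate: real station-interpolated
surfaces and their error structure, lakes and coastlines (and the
associated masking of analog searches over water), sub-50-m microclimate,
multiplicative precipitation change, and inter-model spread of the
scenario ensemble. Passing tests therefore demonstrate the pipeline's
internal correctness and the direction and rough magnitude of
resolution effects on terrain-structured climate — not the specific
kilometre-scale figures of any real network.

## Numerical choices and degenerate inputs

* Grid convention: upper-left origin, row-major, cell-centre registration;
  cell (r, c) has centre $(x_0 + (c - 0.5)s,\; y_0 - (r - 0.5)s)$. All
  distances are centre-to-centre.
* Aggregation blocks at the right/bottom edge average over the cells
  present; an all-nodata block stays nodata.
* I/O uses the plain-text ESRI ASCII grid format with full 17-digit
  precision, so write–read round-trips are bit-exact; polygons travel as
  CSV with a WKT column. A cell size below 1 with corner coordinates
  inside ±361 is rejected as a geographic-CRS grid.
* `paired_velocity_test()` flags zero-variance differences instead of
  erroring; `glm_relative_diff()` reports rank deficiency explicitly and
  drops the scenario factor when only one level is present.
* Velocity means over a reserve use only finite, non-disappeared cells;
  `frac_disappeared` preserves the information that is excluded.

## Problem sizes

The shipped tests and the acceptance script run the full pipeline on
400×400-cell fine grids (a 20-km domain at 50 m) with factor-20
aggregation, 200 reserves, three scenarios and five seeds; the analog
oracle is verified on 200 random instances up to 50×50. These sizes were
chosen so a complete verification runs in a couple of minutes on one core
while every stage still operates in its intended regime (tens of classes
per variable, reserves both above and below the coarse cell size).

## Known limitations

* Analog searches measure straight-line distance; they do not route around
  masked cells, barriers or water.
* Only speed is reported, not bearing, and only the forward
  (present→future) direction is implemented.
* The GLM ignores spatial autocorrelation between reserves; its standard
  errors are anti-conservative for strongly clustered networks.
* Class edges anchored at 0 are a convention; analyses using other anchors
  will differ near bin boundaries by up to one bin width.
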