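# topoclimvel

Fine-grained climate-analog velocity and climate-exposure analysis for
protected-area (PA) networks.

## The problem

Reserves cannot move, but the climates inside them do. The
**climate-analog velocity** measures that displacement: for every grid
cell, find the nearest location whose *future* climate matches the cell's
*present* climate and divide the distance by the years between the two
periods,

    v = d(cell, nearest future analog) / Δt        [km/yr]

where "matching" means falling in the same fixed-width class of a
bioclimatic variable. Cells whose present class occurs nowhere in the
future surface have a *disappearing climate*. Because terrain creates
climate variation at scales of tens of metres (south-facing radiation
loading, cold-air pooling, lapse-rate cooling), the velocity depends
strongly on grid resolution: kilometre-scale surfaces average away the
nearby cool refugia that fine surfaces contain, and so overstate how far
climates must travel.

`topoclimvel` implements the full pipeline for three bioclimatic variables
with established high-latitude relevance —

| variable | meaning | class width |
|---|---|---|
| GDD5 | growing degree days above 5 °C (°C·days), `gdd5()` | 50 |
| T_Jan | mean January temperature (°C), `t_jan()` | 0.5 |
| WAB | climatic water balance = precipitation − PET (mm), `wab()`, with PET = 58.93 · Σₘ max(Tₘ, 0)/12 | 50 |

— at a fine and an areal-mean aggregated coarse resolution (e.g. 50 m vs
1 km), under additive scenario delta fields, and summarises per-reserve
exposure: zonal mean velocities and disappeared fractions, top-5 % velocity
hotspots and their cross-variable overlap, paired fine-vs-coarse t-tests,
a GLM of relative velocity differences on relief, reserve size, elevation
range and scenario, and present-vs-future within-reserve climate-range
overlap and gaps. A synthetic topoclimatic landscape generator (correlated
random DEMs with relief classes, lapse/radiation/cold-pool temperature
terms, orographic precipitation, smooth scenario deltas, random reserve
polygons) makes everything runnable end-to-end with no external data.

Audience: spatial ecologists and conservation scientists quantifying
climate exposure of reserve networks, and anyone studying how raster
resolution distorts climate-change metrics.

## Worked example

Generate landscapes in the three relief classes (flat, undulating,
rugged), run the full analysis on each, and model the fine-vs-coarse
relative differences:

```r
library(topoclimvel)

runs <- lapply(1:3, function(cl)
  run_landscape_analysis(seed = cl, relief_class = cl, n_pas = 100))

p <- runs[[3]]$paired_tests[["RCP4.5"]]
cat(sprintf("rugged, RCP4.5 GDD: mean(coarse - fine) = %.4f km/yr, t = %.1f (n = %d), coarse > fine in %.0f%% of reserves\n",
            p$mean_diff, p$t, p$n, 100 * p$prop_coarse_gt_fine))
#> rugged, RCP4.5 GDD: mean(coarse - fine) = 0.0097 km/yr, t = 11.8 (n = 92), coarse > fine in 93% of reserves

rd <- do.call(rbind, lapply(runs, `[[`, "rd_records"))
fit <- glm_relative_diff(rd)
round(fit$coefficients, 3)
#>                Estimate Std. Error t value Pr(>|t|)
#> (Intercept)       0.137      0.035   3.942    0.000
#> relief            0.026      0.015   1.709    0.088
#> log_area         -0.001      0.008  -0.069    0.945
#> log_elev_range    0.011      0.010   1.074    0.283
#> scenarioRCP4.5   -0.090      0.014  -6.293    0.000
#> scenarioRCP8.5   -0.159      0.017  -9.150    0.000
```

The paired test shows the resolution effect directly: coarse velocities
exceed the fine ones in 93 % of rugged-terrain reserves, because
aggregation erases the nearby topoclimatic analogs. The GLM's positive
`relief` coefficient says the coarse-resolution overstatement grows with
terrain ruggedness (here n = 595 reserve × scenario records).

Within-reserve range overlap shows the same one-way distortion — at 50-m
resolution the water balance still overlaps its present range in most
reserves, at 1 km in none, and where both tracks show a gap the coarse gap
is larger:

```r
s <- runs[[3]]$overlap_summary
s[s$variable == "WAB", ]
#>  variable scenario resolution_track   n n_overlap  mean_gap
#>       WAB   RCP2.6           coarse 100         0  5.107851
#>       WAB   RCP4.5           coarse 100         0 24.617733
#>       WAB   RCP8.5           coarse 100         0 81.867321
#>       WAB   RCP2.6             fine 100       100        NA
#>       WAB   RCP4.5             fine 100        95 11.377933
#>       WAB   RCP8.5             fine 100         9 33.073163
```

Lower-level entry points: `make_dem()`, `make_monthly_climate()`,
`bioclim_set()`, `aggregate_mean()`, `build_scenario()`,
`climate_velocity()`, `zonal_mean()`, `top_fraction()`,
`pa_range_overlap()`. Grids read/write the plain-text ESRI ASCII format
(`read_grid()` / `write_grid()`); reserve polygons travel as CSV with a
WKT column (`read_pa_csv()` / `write_pa_csv()`). See the methods vignette
(`vignettes/velocity-methods.Rmd`) for the models, parameter defaults and
design choices.

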