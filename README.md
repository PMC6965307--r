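# plumepop

Population-exposure relative-risk mapping from source-resolved air
dispersion.

Ambient concentration alone says where a pollutant *is*; exposure risk
needs to know where *people* are at the same time.  `plumepop` implements
a raster pipeline for assessing the relative risk of population exposure
to SO₂ from industrial point sources and road-traffic line sources, aimed
at environmental-health and environmental-justice analyses at fine
(30 m) spatial resolution:

1. **Dispersion** — annual-mean concentrations at discrete receptors from
   a steady-state Gaussian plume (Briggs open-country σ-curves) weighted
   by a climatological wind rose, separately for industrial, vehicle and
   combined sources.
2. **Interpolation** — inverse-distance weighting (IDW) of the receptor
   values onto the continuous analysis grid.
3. **Dasymetric population mapping** — census-block counts for seven
   demographic groups (total; white/black/other races;
   child/elderly/other ages) redistributed to grid cells by land-use
   density fractions, conserving every block total.
4. **Relative risk** — per cell *i* and source *j*,

   R_ij = (pop_i · C_ij) / ( (Σ_i pop_i · C_ij) / n ),

   the population-weighted exposure normalized by its mean over the
   statistical unit (*n* cells, uninhabited cells included), so the risk
   surface averages exactly 1 and R > 1 marks above-average joint
   exposure.

Downstream analyses reproduce the standard work-ups: exact Fisher–Jenks
natural-breaks classification, top-decile hotspot extraction with
centroid-shift distances between concentration and risk hotspots, and
correlation-based source apportionment (Pearson r of single-source vs
combined-source risk per demographic group).

A seeded synthetic-scenario generator (emission inventory, hourly
meteorology, census-block polygons with demographics, categorical land
use) makes every stage testable without external data; real-data runs
accept delimited tables with WKT geometry, GeoJSON block layers and ESRI
ASCII grids sharing one projected CRS.

## Worked example

```r
library(plumepop)

cfg <- scenario_config(extent_km = c(5, 5), grid_resolution_m = 50,
                       n_point_sources = 10, n_road_polylines = 3,
                       n_blocks = 40, total_population = 16000,
                       n_met_hours = 2000, rng_seed = 42)
county <- generate_scenario(cfg)
county
#> <synthetic_scenario> seed 42: 100 x 100 cells @ 50 m, 40 blocks, 16000 persons
#> <emission_inventory> 10 point (237.79 t/yr), 3 line (929.00 t/yr)

run <- run_analysis(county, pipeline_config(seed = 42, scenario = cfg,
                                            receptor_stride = 4, seg_len = 50))
run$hotspots[, c("source", "shift_km")]
#>       source  shift_km
#> 1 industrial 0.9493199
#> 2    vehicle 0.3947106
#> 3   combined 0.3337765

subset(run$apportionment, group == "total")
#>   group     source pearson_r      p_value n_cells status
#> 1 total industrial 0.2312858 1.812245e-73    5982     ok
#> 2 total    vehicle 0.9976033 0.000000e+00    5982     ok
```

The hotspot table says how far the centroid of the top-10 % exposure-risk
area sits from the top-10 % concentration area for each source — here the
industrial hotspot shifts by ~0.95 km once population is taken into
account, because the high-concentration zone near the stack cluster is
not where people live.  The apportionment rows show that combined-source
risk tracks the vehicle source (r ≈ 0.998) far more closely than the
industrial source (r ≈ 0.23): with a 929 : 237.79 t/yr tonnage ratio and
roads running through the populated core, traffic dominates exposure.

`run_pipeline(pipeline_config(seed = 42, out_dir = "out"))` runs the same
chain on the full default county (20 × 20 km at 30 m) and writes the
complete artifact set — 3 concentration rasters, 7 population rasters,
21 risk rasters, natural-breaks legends, hotspot and apportionment
tables — plus a `manifest.tsv` with an MD5 hash per artifact; runs are
bit-reproducible per seed.  A thin command-line wrapper lives at
`inst/cli/plumepop.R`.

Emission-rate bookkeeping uses metric tons over a 365-day year:

```r
format_emission_rate(tons_per_year_to_g_per_s(237.79))  # "7.54"  g/s
format_emission_rate(tons_per_year_to_g_per_s(929))     # "29.45" g/s
```

## Documentation

The methods vignette (`vignettes/population-exposure-risk.Rmd`) describes
the model, its assumptions, every tunable parameter, the synthetic-data
design and the package's numerical choices and limitations.
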