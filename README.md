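# forestcloud

Measuring cloud-cover enhancement over large temperate forests from
geostationary visible-channel imagery — and its loss after storm windthrow.

Large lowland forests (the Landes and Sologne type of landscape: a
100-km-scale forest block inside cropland, no orography) are darker and
rougher than their surroundings. The resulting extra sensible and latent
heat flux favours earlier and more frequent summer shallow-cumulus
development over the forest, organized by a mesoscale forest-breeze
circulation that pushes the preferred cloud formation toward the downwind
forest edge. `forestcloud` provides, for researchers in land–atmosphere
interaction and ecosystem remote sensing, the complete observational
tool-chain for quantifying this effect from 10-bit digital-count imagery at
~1 km / 15-min resolution, plus a seeded synthetic-scene generator with
known ground truth so every stage is testable without satellite data.

## What it computes

* **Empirical cloud detection** (`ecdf_steepest`,
  `build_clearsky_climatology`, `detect_clouds`): a per-pixel clear-sky
  count climatology in (10-day period × hour-of-day) bins, each level taken
  at the steepest section of the bin's empirical CDF — the densest, darkest
  mode, since clouds only brighten the scene — followed by constant-threshold
  masking (`count > clim + 10`).
* **Climatologies and box statistics** (`frequency_map`,
  `box_daily_series`, `dekadal_difference_series`, `diurnal_cycle`,
  `ttest_two_boxes`, `bootstrap_percentile_intervals`, `significant_bins`):
  cloud frequency = fraction of valid daylight (06–18 UTC) slots flagged
  cloudy; forest vs non-forest box comparisons by Welch t-test and seeded
  bootstrap 50/95 percentile intervals.
* **Wind-conditioned composites** (`classify_days`, `composite_frequency`):
  per-wind-class frequency maps with per-class empirical 90th-percentile
  exceedance contours; class maps recombine bit-exactly to the all-days map.
* **Seasonal breakpoint fit** (`fit_squared_sine`, `amplitude_change`): the
  dekadal forest-minus-nonforest difference is modelled as
  `d(t) = c + b·t + A·sin²(π(t − φ))` (period one year); independent fits
  before and after a storm date quantify the amplitude drop with 95%
  confidence intervals.
* **Synthetic scenes** (`build_landcover`, `sim_config`, `simulate_truth`,
  `render_counts`, `simulate_dekadal_difference`): Bernoulli cloud
  occurrence with a configurable JJA forest enhancement (default 0.10, the
  middle of the observed 0.05–0.15 range), wind-displaced enhancement
  fields, a post-storm residual (default 0.020) inside a damage zone, and
  count rendering with additive cloud brightening and Gaussian noise.

## Worked example

A three-year synthetic scene (120×120 km, hourly cadence, storm breakpoint
24 January 2009 inside the record) analysed end to end:

```r
library(forestcloud)
cfg <- list(grid = list(nx = 120L, ny = 120L,
                        forest = c(30L, 90L, 30L, 90L),
                        damage = c(40L, 80L, 40L, 80L)),
            start = "2008-01-01", end = "2010-12-31",
            cadence_minutes = 60L, n_boot = 1000L, seed = 42L)
res <- run_pipeline(cfg, "demo-out")   # ~1 min on one CPU
res$ttest
#> Welch two-sample t-test: t = 13.361, df = 365.0, p = 2e-33 (n = 276, 552)
res$klaus
#> Seasonal amplitude change at 2009-01-24
#>   A_pre  = 0.055 [0.038, 0.071] (n = 38)
#>   A_post = 0.005 [0.003, 0.007] (n = 70)
#>   ratio  = 0.096
res$composite
#> <wind_composite (speed_class), q90 levels>
#>   v < -1           n_days= 75  mean v=-2.32 m/s  level=0.336
#>   -1 <= v <= 1     n_days=111  mean v=-0.05 m/s  level=0.332
#>   v > 1            n_days= 90  mean v=+2.35 m/s  level=0.333
```

Reading the output: daily JJA cloud frequency over the forest box exceeds
the non-forest boxes decisively (t = 13.4, p ≈ 1e-33). The seasonal
amplitude of the dekadal difference collapses by an order of magnitude at
the breakpoint (0.055 → 0.005; the fitted pre-storm amplitude sits below
the configured 0.10 enhancement because the daily wind displacement moves
the enhanced region on and off the fixed analysis box — turn
`wind_displacement_km_per_ms` to 0 to recover the full amplitude). All ten
JJA dekad bins are flagged significant by the paired difference bootstrap
(`res$significant`). Every tabular output, plus a manifest with the seed,
the full configuration and MD5 hashes of all outputs, lands in `demo-out/`;
rerunning with the same config reproduces every file bit-exactly.

A YAML version of this configuration ships in
`inst/extdata/demo_config.yaml`, and `inst/scripts/forestcloud.R` wraps the
pipeline for shell use:

```sh
Rscript inst/scripts/forestcloud.R run --config inst/extdata/demo_config.yaml --out demo-out
```

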