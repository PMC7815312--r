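# omzshark

Quantifying how an oxygen minimum zone (OMZ) compresses the vertical
habitat of a pelagic shark and raises its exposure to surface longline
fisheries.

Where hypoxic water shoals, the oxygenated surface layer thins. A shark
whose dives are limited by dissolved oxygen (DO) at depth is squeezed
toward the surface — and toward the depth of baited longline hooks. This
package implements the full analytical chain for that question, for anyone
working with satellite-tag tracks, gridded ocean fields, vessel GPS
streams, and catch logbooks:

* **Track processing** — location-class filtering, a 3 m s⁻¹ great-circle
  speed filter, daily regularization with great-circle gap interpolation
  and 20-day segment splitting.
* **Environmental matching** — 3×5-pixel box averages of gridded DO,
  temperature, salinity and productivity around each position; oxygen unit
  conversions (molar volume 22.392 l mol⁻¹); pO₂ from the Garcia–Gordon
  solubility fit, `pO2 = (DO/DOsat) · 0.20946 · (101.325 − pH2O)` kPa; OMZ
  classification as DO(100 m) < 3.5 ml l⁻¹.
* **Movement null model** — correlated random walks resampling each
  track's own step lengths and bearings; one-sided empirical test of OMZ
  residency, `p = (1 + #{replicates ≥ real}) / (n + 1)`.
* **Dive summaries** — time-at-depth above 250 m, days with dives below
  600 m, maximum daily dive (MDD) depth by zone, and the
  habitat-compression percentage `100·(1 − MDD_in/MDD_out)`.
* **Habitat model** — a Gaussian additive model
  `MDD ~ s(DO₁₀₀) + s(SST) + s(NPP₁₀₀) + … + (1|shark)` (mgcv), backward
  AIC selection with linear-replacement and significance confirmation,
  partial-effect threshold/optimum recovery, and 1° spatial prediction
  capped at the mixed layer depth.
* **VMS analysis** — detection of V-shaped longline deployments
  (>130° turns, 80–100 km legs, endpoint check), daily-centroid effort
  grids, area-restricted-search fishing intensity, Mann–Whitney
  OMZ-vs-normoxic comparisons.
* **CPUE analysis** — 1° catch-per-unit-effort grids, west–east transects
  against DO at 100 m, and quadratic fits `log₁₀CPUE = c₀ + c₁·DO + c₂·DO²`
  whose vertex `−c₁/(2c₂)` estimates the DO of peak catches.

A synthetic-data module (`gen_env_field()`, `gen_shark_track()`,
`gen_vessel_track()`, `gen_logbook()`) generates every input with the
statistical structure the analysis assumes, so the whole pipeline runs and
is tested without any external download. The methods vignette
(`vignettes/omz-habitat-compression.Rmd`) documents every model,
convention, and design choice.

## Worked example

```r
library(omzshark)

# a synthetic OMZ system and one shark tracked over it
env <- gen_env_field(env_grid_spec(lon_range = c(-30, -10),
                                   lat_range = c(2, 22),
                                   horizontal_resolution = 0.5))
shark <- gen_shark_track(env, shark_behavior_spec(seed = 7), n_days = 60)

# residency vs the correlated-random-walk null
crw_omz_test(shark$track, env, n_replicates = 100, seed = 3)
#> CRW residency test: 100 replicates
#>   real proportion of days over OMZ: 0.867
#>   replicate mean: 0.795 (range 0.433 - 1 )
#>   one-sided empirical p: 0.426

# vertical summary of the packaged reference table (10 PSAT-tracked
# blue sharks, inside vs outside the OMZ area)
s <- summarize_vertical(reference_vertical_summary())
round(s[, c("max_depth_omz", "max_depth_outside")], 1)
#>      max_depth_omz max_depth_outside
#> mean         754.0            1250.3
#> sd           419.5             316.4
pct_reduction(754.0, 1250.3)   # habitat compression
#> [1] 39.69608  — i.e. mean maximum dive depth is ~40% shallower over the OMZ

# DO concentration supporting peak catches, from a transect quadratic
quadratic_peak(c(1.833, 1.082, -0.1539))
#> [1] 3.51527
```

The shark here shows high OMZ residency (0.87) but its null walks do too
(started over a basin-scale OMZ, random walks rarely leave), so the test is
rightly non-significant — see the vignette on when the residency null is
informative.

## The analysis workflow

The `analysis/` scripts run the chain end to end on synthetic data,
printing what each stage finds and writing tables under `results/`:

```sh
Rscript analysis/01_simulate.R        # environment, sharks, vessels, logbook
Rscript analysis/02_process_tracks.R  # clean -> daily -> env-matched tracks
Rscript analysis/03_crw_residency.R   # residency null model per shark
Rscript analysis/04_dive_summary.R    # zone summaries, compression %
Rscript analysis/05_habitat_model.R   # additive MDD model + capped map
Rscript analysis/06_vms_effort.R      # set detection, effort, intensity
Rscript analysis/07_cpue_transects.R  # CPUE transects, DO of peak catch
```

Stage 7, for instance, recovers the logbook generator's prescribed peak:
`all cells pooled (n = 793): peak CPUE at DO = 3.01 ml/l (generative peak 3.0)`.

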