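---
title: "Methods: OMZ habitat compression and fishing exposure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: OMZ habitat compression and fishing exposure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(omzshark)
```

## The problem

Oxygen minimum zones (OMZs) are mid-water layers of persistently hypoxic
water. Where an OMZ shoals, the oxygenated surface layer thins, and pelagic
fish with high oxygen demands are squeezed toward the surface — *habitat
compression*. For a commercially exploited shark this is a double hazard:
less vertical habitat, and more overlap with surface longline gear. This
package implements the full analytical chain needed to quantify both sides
of that interaction for satellite-tagged blue sharks in an eastern-Atlantic
style OMZ system: tag-track processing, environmental matching, a
movement-null model of OMZ residency, dive-depth summaries, an additive
habitat model with spatial prediction, longline-set detection from vessel
GPS, and catch-per-unit-effort (CPUE) analysis against dissolved oxygen
(DO).

Everything runs on synthetic data: the real tag, ocean-model, vessel
monitoring system (VMS) and logbook inputs are not publicly deposited, so
the `synthetic_data` functions generate inputs with the statistical
structure the analysis assumes. The `analysis/` scripts walk through the
chain; the testthat suite checks every stage against independent oracles.

## The OMZ definition and oxygen physics

A position is *inside the OMZ area* when DO at 100 m is strictly below
3.5 ml O~2~ l^−1^ (`classify_omz()`); the boundary value itself counts as
outside ("decreased below" is read strictly). The same 3.5 ml l^−1^ surface
at 100 m is the lower habitat boundary used for mapping, fleet comparison,
and the habitat model's expected DO threshold.

Unit conversions use the O~2~ molar volume 22.392 l mol^−1^
(1 ml l^−1^ = 44.659 µmol l^−1^; 1 mg l^−1^ = 0.69978 ml l^−1^), with
per-kilogram conversions through EOS-80 surface seawater density. The
partial pressure of oxygen is

pO~2~ = (DO / DO~sat~(T, S)) × 0.20946 × (101.325 − p~H2O~(T, S)) kPa,

with DO~sat~ from the Garcia–Gordon fit to the Benson–Krause data (ml l^−1^
coefficients; the implementation reproduces the published check value
C(10, 35) = 6.315 ml l^−1^) and seawater vapour pressure from the
Weiss–Price formulation. Total pressure is fixed at 1 atm — values are
referenced to the surface, with no hydrostatic correction; this matches the
convention of the standard respirometry tools and keeps pO~2~ exactly
linear in DO at fixed (T, S). Box-averaged temperature and salinity are
averaged *first* and then converted (the alternative order differs only at
second order in the within-box variability).

Environmental matching (`box_average()`) averages each variable over grid
pixels whose centres fall in a closed box of ±0.375° longitude × ±0.625°
latitude around the position — a 3 × 5 pixel neighbourhood on the native
0.25° grid — absorbing geolocation error. Pixels with missing values drop
out of that variable's mean; boxes clipped by the domain edge average what
remains.

## Track processing

Raw Argos fixes lose class-Z rows, then pass a greedy forward 3 m s^−1^
great-circle speed filter (first fix always kept, so no retained pair
exceeds the limit, and the filter is idempotent). Days with several fixes
collapse to their centroid — the simplest defensible one-position-per-day
regularizer, standing in for state-space smoothing, which is out of scope.
Missing runs of up to 20 days are filled along the great circle between the
flanking daily positions (a gap of exactly 20 days is still interpolated;
longer gaps split the track into segments). All geometry is spherical
(haversine, R = 6371 km); the errors are far below geolocation error.

## The correlated-random-walk residency null

To ask whether a shark spent more days over the OMZ than its own movement
statistics predict, `crw_omz_test()` resamples the track's empirical step
lengths and *bearings* (not turning angles, preserving the track's overall
directional structure) independently and with replacement, rebuilding 100
replicate walks from the real start point with the real number of
locations. The one-sided empirical p-value uses the add-one rule
p = (1 + #{replicates ≥ real}) / (n + 1), with ties counting against
rejection. The replicates are scored against the same static OMZ mask as
the real track.

Two structural properties matter for interpretation:

* the real track uses each of its steps exactly once (a permutation),
  while replicates resample with replacement, so replicate summaries have
  slightly heavier tails and the test is *conservative* — measured
  rejection rates under the null sit near 2% at a nominal 5%;
* the test has power only when the null walk's diffusion length over the
  track (≈ step scale × √days) exceeds the OMZ extent. Against a
  basin-scale OMZ both the shark and its nulls stay inside and p ≈ 1 —
  visible in `analysis/03_crw_residency.R`, where sharks tagged over the
  wide synthetic OMZ are never significant. The calibration and power
  tests therefore use a compact OMZ patch (radius 3°) with 90-day tracks
  and 45 km steps, where the property is identifiable.

## Dive summaries

Tags report daily time-at-depth (TAD) histograms over fixed depth classes
(two deployment-year schemes are built in) and a daily maximum dive depth
(MDD). `pct_time_upper()` sums whole classes above a cutoff that must be a
class edge — no within-class interpolation. Deep-dive counts are days with
MDD below the threshold (daily summaries cannot see multiple deep
excursions within a day; a day counts once). Cross-shark summaries use the
sample (n−1) SD and ignore absent zone cells (tags that reported in only
one zone) — the convention that reproduces the reference table's printed
means exactly. Habitat compression is 100 × (1 − MDD~inside~/MDD~outside~)
applied to the zone means. The boundary-day comparison pairs the day before
each OMZ entry with the day after it, dropping entries that lack either
flanking day.

## The additive habitat model

`fit_mdd_model()` fits a Gaussian identity-link additive model of MDD depth
with a penalized cubic regression spline per candidate covariate (basis
dimension 10 by default), optional tensor-product interactions
(SST × DO, NPP × DO, SST × NPP), and a per-shark random intercept
(`s(shark_id, bs = "re")`). Before fitting, the top 10% of MDD depths are
discarded as outliers (strictly above the empirical 0.90 quantile; ties at
the quantile are kept).

Structure selection is backward elimination on AIC over maximum-likelihood
fits, followed by replacing effectively-linear smooths with linear terms
when AIC prefers it, and finally a confirmation prune of any term whose
approximate test p-value exceeds 0.01. The confirmation step is essential:
plain backward AIC retains a pure-noise smooth with probability
≈ P(χ²₁ > 2) ≈ 16% per candidate, which makes clean structure recovery
across several noise covariates essentially impossible; requiring
significance as well brings the per-term false-retention rate to ~1–2%.
The 0.01 level was chosen from that power analysis, before any recovery
experiment was run. The selected structure is refit by REML for reporting;
residual diagnostics (lag-1 autocorrelation, residual-vs-fitted slope) are
attached rather than folded into a weighted refit, since they affect
standard errors, not structure selection or response shapes.

The fitted DO threshold is estimated from the DO partial effect by a
broken-stick fit (continuous piecewise-linear, knot chosen by least squares
over the inner 80% of the range) — markedly more stable than locating the
curvature maximum at realistic basis sizes. The SST optimum is the argmax
of the SST partial effect.

Spatial prediction (`predict_mdd_map()`) box-averages the environment over
1° cells, predicts from the fixed effects only, and caps each prediction at
the local mixed layer depth (MLD). The MLD criterion is the standard
oceanographic ΔT = 0.2 °C relative to 10 m, linearly interpolated between
levels; isothermal columns return the deepest level with a flag. When the
surface mixed layer is shallow — as over a strong OMZ — capping binds in
most cells, which is the habitat-compression signal itself.

One caveat the workflow makes visible: covariates sampled *along tracks* in
an OMZ system are strongly collinear (DO, SST and NPP all vary along the
same radial gradient), so on-track frames often collapse to a single DO
smooth. The selection-consistency experiments therefore draw covariates
independently over their realistic ranges, which is the regime in which
"retains the true drivers, drops the noise" is a well-posed question.

## Longline-set detection and fishing grids

A longline deployment traces a "V": steam out 80–100 km laying the line,
turn nearly through reversal, retrace to haul. `detect_longline_sets()`
scans interior pings for heading deviations above 130° (deviation from
straight-ahead; a 120° turn is below the rule), walks backward and forward
from each candidate until the accumulated along-track distance exceeds the
longline length, and accepts the candidate only if the two walk endpoints
are within 25% of the upper line-length bound of each other. The walk uses
the *lower* line-length bound: the true length of any one line is unknown
within 80–100 km, and walking the upper bound runs off the deployment legs
into transit whenever the line is short, scattering the endpoints
(measured recall drops from 0.95 to 0.66). Overlapping candidates keep the
sharper turn; each ping belongs to at most one set.

Fishing effort is daily-centroid based: per vessel and calendar day, one
centroid, one effort-day, in half-open 1° cells keyed by the lower-left
corner — so effort-days are conserved exactly. Fishing intensity
operationalizes area-restricted search (ARS) as same-vessel fishing
locations on *adjacent calendar days within 30 km*; intensity per cell is
ARS locations over all locations. The radius and adjacency rule are an
explicit operationalization (the qualitative description — repeated,
localised daily deployment — names no formula), and both are configurable.
Zone comparisons use two-sided Mann–Whitney tests; completely tied samples
return p = 1 by convention.

## CPUE transects and the DO of peak catches

Logbook records aggregate to 1° cells (mean CPUE = total biomass / total
sets; one set is one day of effort). Transects extract a cell-centre
latitude row west-to-east with DO at 100 m attached, plus the cumulative
mean CPUE along the row. The DO of peak catch is the vertex −c₁/(2c₂) of an
ordinary least-squares quadratic of log₁₀ CPUE on DO, defined only for
concave fits; zero-CPUE cells are excluded by default (the log is
undefined), with a labelled non-canonical `+1 kg` offset mode. Cells are
weighted equally. Vertices are reported to two decimals.

## The synthetic study system

`gen_env_field()` blends two end-member water columns — oxycline at 60 m
vs 400 m, SST 25.5 vs 21 °C, NPP peak 0.009 vs 0.001 g l^−1^ d^−1^ (the
nine-fold inside/outside contrast) — through a radially symmetric logistic
ramp of width 0.15 × radius around the OMZ centre, plus a smooth seeded
multiplicative noise surface. DO is monotone non-increasing with depth in
every column and never exceeds the column's surface value; the realized
3.5 ml l^−1^ contour at 100 m sits at about 0.73 × the nominal radius.
Defaults (0.25° resolution, 14 depth levels to 1700 m, domain 45–10°W ×
0–25°N) were chosen once to match the study system's magnitudes and are
not revisited by any test.

`gen_shark_track()` moves a shark by a correlated random walk (Weibull step
lengths, wrapped-normal turning; `bearing_concentration = 0` gives
independent uniform bearings) with an optional OMZ residency bias
(probability 1 − e^−b^ of rejecting a proposed exit), reflection at the
domain boundary, and generates each day's MDD from the deterministic
response — piecewise-linear shrinkage below the DO threshold of
3.5 ml l^−1^, a tent-shaped SST response peaking at 24 °C (+3%/°C below,
−8%/°C above, so the optimum is an interior maximum, matching the shape the
habitat model is asked to recover), linear shrinkage in NPP — times
lognormal noise floored at 10 m. TAD histograms allocate exactly 100%
across the classes reachable at that day's MDD with exponential surface
weighting. `sim_mdd_frame()` draws the same response over independently
sampled covariates plus pure-noise columns, for the selection experiments.

`gen_vessel_track()` builds trips of transit legs and V-deployments
(outbound leg of the drawn line length, slow soak drift roughly along the
outbound heading, haul to within 4 km of the start), pings hourly with
0.15 km GPS noise — inside the stated sub-500 m VMS accuracy. Deployment
headings stay within ±100° of the arrival course so the only near-reversal
in a deployment is the V apex. `gen_logbook()` scatters sets with log₁₀
biomass quadratic in local DO at 100 m around a prescribed peak
(default 3.0 ml l^−1^), with Gaussian noise (SD 0.15 decades).

What the generators deliberately do **not** emulate: mesoscale eddies,
seasonal cycles, ocean-model numerics, tag failure modes, day/night dive
structure, or fleet economics. Passing tests therefore demonstrate that the
*methods* recover known structure under the stated statistical assumptions,
not that real data would behave as cleanly.

## Problem sizes and numerical choices

The test suite runs the heavy experiments at sizes chosen to make their
statistical targets identifiable at modest cost: 500 null sharks × 100
replicates for calibration; 30 biased sharks for power; 100 vessel trips
(300 sets) for detector fidelity; 50 simulated frames of 8 sharks × 60 days
(≈ 430 rows after outlier removal, basis dimension 8) for selection
recovery. Other conventions: strict inequality at the 3.5 ml l^−1^ OMZ
threshold; quantile ties kept in the outlier filter; the 20-day gap rule
splits only strictly longer gaps; complete ties give p = 1 in both the
residency and zone tests; all randomness flows from explicit integer seeds
and every generator is a pure function of (spec, seed).

## Known limitations

* The residency null is conservative (permutation-vs-bootstrap asymmetry
  above) and uninformative against regions larger than the track's
  diffusion length.
* Deep-dive counts from daily summaries undercount days with several deep
  excursions.
* On-track covariate collinearity can merge the three habitat drivers into
  a single DO effect; the model reports what the data can identify.
* The ARS rule is an operationalization, not the original authors' exact
  clustering criterion; intensity values depend on the 30 km radius.
* pO~2~ is referenced to surface pressure; at-depth in-situ partial
  pressures would need a hydrostatic correction.
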