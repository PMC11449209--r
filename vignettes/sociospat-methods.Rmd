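---
title: "Methods: socio-spatial comparison of central-place foragers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: socio-spatial comparison of central-place foragers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sociospat)
```

`sociospat` compares how the members of a community distribute themselves
over a landscape: how far apart they are moment to moment, how far each
travels from the day's starting point, and how much of the daily visited
landscape any two members have in common. This vignette is the package's
account of the models and the design choices behind them; every number shown
here is computed by the code in this document or by the test suite.

## 1. The canonical trajectory representation

All statistics consume one representation: per-community sets of
individual-day trajectories on a uniform **5-second epoch grid** in a planar
frame.

**Projection.** Fixes arrive as WGS84 longitude/latitude and are projected
with a transverse-Mercator (UTM) transformation implemented from the
Karney–Krüger series to order $n^6$; forward and inverse are mutual inverses
to below $10^{-9}$ degrees, and planar distances agree with geodesic
distances to well under 1% at the sub-20-km extents of daily foraging, which
is why proximity, displacement and rasterization can all share one planar
geometry instead of mixing haversine and grid arithmetic. With
`crs = "auto"` the zone containing the centroid of the fixes is chosen;
spans over 6° of longitude warn.

**Resampling.** Output epochs are the multiples of 5 s spanned by the input.
At each epoch the fix is the input fix at that instant when one exists;
otherwise it is linearly interpolated between the bracketing fixes provided
the bracket spans at most `maxGapS` (default 300 s, i.e. gaps up to five
minutes are bridged, longer outages leave epochs absent). Pure decimation
would discard four-fifths of 1-Hz input whenever the recorder's phase is off
the grid; bounded interpolation keeps it. Duplicate fixes at one epoch keep
the first (deterministic and order-stable); resampling an already-gridded
track is the identity, so pipelines can be re-entered safely.

**Local time.** Days split at local midnight and hour bins are local hours,
using a fixed configurable UTC offset (default +3 h, East Africa Time).
Hour-of-day structure — morning departure, midday dispersal, evening return —
only exists in local time, so a fixed offset is part of the dataset, not of
each call.

**Exclusions.** Track filtering is config-driven: plain-text rules
`id,reason` or `id,date,reason`, applied with a logged reason per removal.
No automatic quality threshold is imposed, because defensible cutoffs
(minimum coverage hours, error screens) are dataset-specific; the rules for
the public Mpala olive-baboon Movebank release ship with the package
(`mpalaExclusions()`).

## 2. Proximity, displacement

`dyadDistances()` evaluates, for every unordered pair and every epoch
present in both trajectories (and only those), the planar Euclidean
distance. Summaries pool **dyad-epoch samples** — not per-dyad means of
means — so a community is described by one sample population, and
`proximityAccumulator()` keeps those summaries streamable: exact running
moments and maximum plus a fixed-width 0.1 m histogram for the median, with
raw values retained (and the median exact) below $10^6$ samples. Datasets at
this sampling rate reach $10^8$ dyad-epochs, which must not need to be held
in memory at once. Hourly quantiles use the standard linear-interpolation
(type-7) definition; no convention is universal, so the choice is fixed and
documented for reproducibility.

`dayMetrics()` computes the day range as the sum of planar steps between
consecutive present epochs — a recording gap contributes the single straight
step between its flanking fixes — together with start–end displacement and
maximum distance from the day's first fix. Day range is computed on the 5-s
track **without smoothing**: high-frequency tracks read longer than coarsely
sampled ones because they resolve small-scale meandering and measurement
dither, and the package reproduces rather than corrects that property of the
sampling design (an optional odd-width median filter, off by default, is
exposed for sensitivity analysis). The "day's starting point" is simply the
first present epoch — for camp-based foragers this is in practice the
wearer's hearth — and `radialTimeProfile()` pools per-epoch distances from it
across all individual-days, so its radii are time-weighted by construction.

## 3. Landscape visitation and overlap

The visitation raster of an individual-day is the set of grid cells touched
by its path. Three choices matter:

- **Cell size.** The field convention "10 m² cell" is read as a 10 m × 10 m
  cell (100 m² area) — side-length shorthand, consistent with companion
  work. This is the most consequential single interpretation in the package,
  so `gridSpec(cellSizeM = ...)` makes it a first-class knob (pass
  `sqrt(10)` for the literal-area reading).
- **Grid anchor.** Cell boundaries sit at integer multiples of the cell size
  in the projected CRS. The alternative — anchoring at the data's bounding
  box — makes cell sets depend on which subset of data is loaded;
  `snapGridToData()` exists for sensitivity analysis only.
- **Path vs points.** By default every cell the straight segment between
  consecutive epochs touches registers (supercover traversal); cells are
  half-open $[i\,c,(i{+}1)c)$ squares, and the implementation computes, by
  crossing-ordered enumeration in exact arithmetic, precisely the cells
  containing at least one point of the polyline. Epoch gaps longer than the
  resampling bound are *not* bridged. `mode = "points"` registers only
  fix-containing cells, since a rasterization of point locations is a
  plausible alternative reading of common GIS workflows; path mode is the
  default because the quantity of interest is the land the path of travel
  intersected. The traversal is validated against a dense point-walker
  oracle (1 cm steps, with exact Liang–Barsky clipping confirming any cell
  whose intersection is shorter than one walker step) rather than trusted by
  construction.

Overlap statistics are exact integer set arithmetic on cell keys. For a
dyad-day, `fraction_similar` $= n_d/n_e$ and `fraction_different`
$= (n_b+n_c)/n_e$ sum to one identically; the cells-visited-by-neither set
is never materialized because the landscape is unbounded. Dyads are compared
within a calendar day only, and only within a community — cross-day and
cross-community overlap answer different questions. `explorationCurve()`
unions the per-individual cell sets in a seeded random order (one order per
day by default); its final value is the order-invariant union size.
`sexPartition()` unions cells by sex across all days before partitioning,
and `averagePartitions()` averages the three fractions across communities
with equal weight per community, renormalizing only if floating-point drift
exceeds $10^{-9}$.

## 4. The synthetic archetypes

The simulator exists so that every statistic has a no-download input with
known structure, emulating the two community archetypes the statistics are
designed to separate. Both archetypes share mechanics: fixes on the 5-s
grid, all randomness derived from one seed (per-individual and per-day
substreams by stable hashing of identifiers, so output is independent of
iteration order), and an autocorrelated GPS measurement dither (OU process,
s.d. 3 m, 120 s relaxation per axis) — wearable-GPS error is autocorrelated,
not white, and at 5-s sampling it contributes a few kilometres of apparent
path per day, just as it does in real high-frequency tracking.

**Troop** (`troopConfig()`): one centroid leaves the sleep site, traverses a
smooth closed loop (a Fourier-perturbed circle through the sleep site, so
start–end displacement is near zero by construction while the day's travel
is substantial), pauses for about five 30–60-minute foraging/resting stops,
and dwells at the sleep site for the remaining time. Each member is the
centroid plus an independent mean-reverting 2-D offset with stationary
per-axis s.d. `spreadSigmaM`, simulated at 120-s nodes and interpolated to
the grid so tracks stay smooth at fix scale (the node interpolation shrinks
the stationary s.d. by ~2%, folded into the tolerance of every analytic
check). Defaults: 10 individuals, 3 days, 12-h recording window.
`spreadSigmaM = 14` is the value whose Rayleigh dyad-distance median
$2\sigma\sqrt{\ln 2}$ lies near the ~23 m medians reported for cohesive
baboon troops, and the loop radius (250 m) and centroid speed (0.25 m/s)
were chosen so that the summed day range lands near 10.5 km — the scale
reported for such troops at this sampling rate. Because member offsets are
independent and isotropic, the dyadic distance is Rayleigh with scale
$\sigma\sqrt2$, giving the closed-form median the tests check against
simulation.

**Band** (`bandConfig()`): members belong to a fixed camp (individual hearth
points scattered within ~15 m). Each individual-day either stays in camp
(probability 0.25, pottering around the hearth with a 4-m OU jitter) or
draws a trip: females travel in groups of 3 sharing one path (departing
07:30–09:00, returning 12:30–15:00, up to 4 km from camp, low sinuosity)
with 5-m individual jitter; males travel solo (07:00–08:30 out, 14:30–17:30
back, up to 8 km, high sinuosity). A trip is an out-and-back radial profile
with smooth Fourier lateral wander scaled by the sinuosity parameter, and
the distance from camp is hard-capped at the sex's maximum even after
jitter and noise. Trip-duration and group-size distributions for real
forager camps are not published at this resolution; the windows above are
free parameters chosen to match the ethnographic pattern of morning
departure, earlier female return, and evening re-aggregation.

**What the simulator does not emulate.** No habitat, resources, terrain or
trail network; no predator avoidance or energetics; no coordination between
trip groups. Real forager camps reuse trails and water points, so real
cross-trip and cross-sex raster overlap is higher than the simulator's
near-zero; real troops coordinate progressions along shared routes, which
the independent-offset model cannot produce. Passing tests therefore show
that the *statistics* behave correctly on data with known structure — they
do not show that the generator reproduces any particular population's
values, and the archetype-separation checks are deliberately ordinal (troop
median shared fraction above 0.2 and above the band's at 5, 10 and 20 m
cells; band median dyadic distance above 250 m) rather than point targets.

```{r archetypes}
troop <- simulateTroop(troopConfig(nIndividuals = 6, nDays = 1, seed = 1))
band <- simulateBand(bandConfig(nIndividuals = 8, nDays = 1, seed = 1))
proximitySummary(dyadDistances(troop))
proximitySummary(dyadDistances(band))
grid <- gridSpec(10)
c(troop = median(dyadOverlapTable(troop, grid)$fraction_similar),
  band = median(dyadOverlapTable(band, grid)$fraction_similar))
```

## 5. Numerical choices and degenerate inputs

- Quantiles: type 7 everywhere; the radial profile at level 1 returns the
  exact maximum.
- Cell keys pack (col, row) into one double exactly for indices below
  $2^{25}$ — beyond any metre-scale grid in a UTM zone.
- Overlap fractions divide only after integer counting, so
  `fraction_similar + fraction_different == 1` holds exactly.
- Single-fix days are flagged degenerate with zero metrics rather than
  dropped silently; all-fixes-at-one-instant is an error.
- A dyad with no shared epochs yields an empty series and is logged, not an
  error.
- Individuals lacking a demographics row are excluded with a warning at
  dataset assembly; unknown sex excludes an individual from the sex
  partition only.
- Exclusion rules naming unknown individuals warn rather than error, so one
  rule file can serve many data subsets.

## 6. The pipeline

`runPipeline()` drives ingest → proximity → displacement → overlap →
exploration → sex partition for each configured community and writes tidy
CSV/JSON plus a cross-community comparison. The config (list, YAML or JSON)
is validated — including the existence of every referenced path — before any
computation, is copied verbatim into the output directory, and fully
determines the run: reruns are byte-identical. Each run writes a manifest
(package version, config hash, seeds) and a line-delimited JSON log; a stage
failure aborts naming the stage and community. Plots
(`plotHourlyQuantiles()`, `plotDayPaths()`) are conveniences; every reported
quantity is tabular.

## 7. Test problem sizes

The suite exercises: projection round-trips on 200 random points; 200
random toy paths against the rasterization oracle; proximity brute-force
recomputation on 3 × 30-fix days; archetype checks on one-to-three simulated
days of 6–16 individuals (the default conditions); and the full pipeline on
two small simulated communities. These sizes were chosen so the whole suite
runs in well under a minute while every claim above is still load-bearing;
`scripts/acceptance.R` re-runs the default-condition archetype comparison
end to end.

## 8. Known limitations

- Linear interpolation of lon/lat during resampling is exact only at small
  extents (it is paired with planar interpolation of x/y; at daily foraging
  scales the discrepancy is far below GPS error).
- The histogram median is exact to 0.1 m above $10^6$ pooled samples.
- UTM distance distortion (up to ~0.1% in-zone) is inherited by all metric
  statistics; tests bound it against a geodesic oracle.
- GeoTIFF raster export is not provided; cell sets export as CSV via
  `visitationTable()`/`decodeCellKeys()`.
- The simulator's defaults describe plausible field conditions, not fitted
  estimates of any real population (section 4).
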