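---
title: "Modelling flood impacts on walking and referral access to maternal care"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling flood impacts on walking and referral access to maternal care}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(floodAccess)
```

## The problem

On seasonally flooded plains, a woman's ability to reach maternal healthcare
is not a fixed property of geography: the annual floodwave redraws the
accessible landscape every month. `floodAccess` couples monthly hydrodynamic
flood fields — rasters of floodwater depth (m) and velocity (m s^-1^) — with
two access models:

* **Walking access** (raster model): women of reproductive age walk from
  their home grid cell to the nearest facility offering a given maternal
  service — a delivery site (skilled birth attendant), an emergency
  obstetric care (EmOC) location, or a maternity waiting shelter (MWS).
* **Emergency referrals** (network model): a woman who develops obstetric
  complications at a delivery site is driven by 4WD to the nearest EmOC
  location over a road network whose per-segment speeds are conditioned on
  the month's flood state.

The two are joined by a population-weighted coupling: referral capability is
counted only for the delivery sites that women can actually walk to in that
month, so the monthly referral summary reflects the whole chain from home to
definitive care.

## Walking model

### Impedance surface

Each month's impedance surface stores per-cell traversal time $\tau$ in
seconds per metre. Layering order (later layers overwrite earlier ones):

1. background: off-road walking at 3 km h^-1^ ($\tau = 1.2$ s m^-1^),
2. road-traced cells: on-road walking at 4 km h^-1^ ($\tau = 0.9$ s m^-1^),
3. permanent waterbody buffers (half the average width either side of the
   centreline): impassable,
4. cells whose flood depth strictly exceeds 1 cm: impassable.

The speeds are deliberately below the conventional 5 km h^-1^ average to
reflect reduced mobility in late pregnancy. The published overlap rule for
impedance mosaics ("keep the maximum impedance") is implemented as priority
layering: read literally, a maximum rule would let slow background override
fast roads; layering reproduces the evident intent — roads speed walking,
water blocks it. Cells that are wet but at or below the 1 cm limit walk at
the unchanged underlying speed: the source methodology specifies only the
impassability threshold and no wet-walking slowdown, and we do not invent
one. Slope and land-use friction are omitted (the modelled floodplain is
extremely flat with near-homogeneous land use), and the causeway's cells are
treated like any other road cell for walking.

### Accumulated cost

Travel times are exact multi-source shortest paths on the grid move graph
with 16-neighbour connectivity: 4 orthogonal, 4 diagonal and 8 knight moves,
which reduces the metric distortion of 8-neighbour routing. A move between
cells $a, b$ costs

$$ L \cdot \frac{\tau_a + \tau_b}{2}, \qquad
   L = \text{cellSize} \times \{1, \sqrt2, \sqrt5\}. $$

Two numerical conventions matter:

* **Knight interior blocking.** A knight move is admissible only when both
  interior cells crossed by the straight centre-to-centre segment are
  passable. Without this, routes tunnel through one-cell-wide rivers, which
  destroys barrier fidelity at exactly the feature this model exists for.
* **Endpoint-average weighting.** Reference implementations of 16-neighbour
  cost accumulation do not publish their interior-cell weighting for knight
  moves; endpoint averaging keeps the metric consistent across all three
  step lengths. The engine is label-setting (each cell finalised once) and
  the test suite verifies it cell-for-cell against an independently
  constructed move graph solved by `igraph`.

Facilities are seeded as zero-cost sources (one multi-source run per service
class) rather than running one search per population point; with an
isotropic, symmetric metric this yields identical nearest-facility times at
a fraction of the cost. Nearest-facility ties break toward the
lexicographically smaller facility id so outputs are deterministic. A
facility sitting on an impassable cell that month is dropped from the source
set and reported; if an entire service class is flooded out, the month's
cost surface is all-unreachable rather than an error, so the 13-month loop
always completes.

Walking times are binned with inclusive upper bounds — 7200 s still counts
as timely two-hour access — into `<=60 min`, `61-120 min`, `>120 min` and
`unreachable`.

## Driving model

Each road segment carries a class with flood-conditioned speeds (km h^-1^):

| class            | dry | wet  | flooded | deeply flooded |
|------------------|-----|------|---------|----------------|
| primary          | 80  | 26.7 | 8       | 5              |
| secondary        | 50  | 16.7 | 8       | 5              |
| track            | 30  | 10   | 8       | 5              |
| water crossing   | 15  | 5    | 8       | 5              |
| elevated highway | 120 | —    | —       | —              |

Depth/velocity are sampled along each segment at half the flood cell size
and the worst point governs the whole segment — one drowned ford blocks the
road, which is how fords behave; long segments should be pre-split at
junctions. States: wet for $0 < D \le 0.01$ m, flooded for
$0.01 < D < 0.1$ m, deeply flooded for $0.1 \le D < 0.5$ m, impassable at
$D \ge 0.5$ m or $V \ge 1.0$ m s^-1^ (vehicular stability criteria; the
velocity bound is deliberately more conservative than the usual guidance).
Boundary cases fall to the more hazardous category so the classification
errs conservative. The elevated causeway is exempt. Two published quirks are
kept as printed rather than "corrected": the wet speeds are reductions *to*
roughly one third (80 to 26.7), not *by* one third, and the water-crossing
wet speed (5) sits below its flooded speed (8); both are fully overridable
through `speedRules()`.

The monthly graph drops impassable segments, splits the rest at every
mutual intersection, and snaps each delivery/EmOC facility to the nearest
passable road point within 250 m (configurable). The connector contributes
zero minutes — the model measures facility-to-facility drive time, and the
last-metre approach is unmodelled. Facilities beyond tolerance are
road-disconnected for the month. Origin–destination minutes come from
Dijkstra runs over the undirected graph; the golden hour is inclusive
(60.0 min is timely), and a delivery site that itself provides EmOC is
`self_emoc` with zero minutes (no road referral assumed).

## Coupling

Each woman is assigned to her nearest *reachable* delivery site by any
finite walking time — not only timely ones — because the coupling contrasts
timely care with complete isolation. She is then counted once per month:

* `no_delivery_access` — cannot walk to any delivery site,
* `site_cannot_refer` — her site has no road path to EmOC,
* `referral_late` — referral takes over an hour,
* `referral_timely` — within the golden hour, or on-site EmOC.

The categories partition the women total exactly, and `no_delivery_access`
equals the walking model's unreachable count by construction; both
identities are tested exactly, not within tolerance. Percentages are kept at
full precision internally and rounded to one decimal only in the CSV
outputs, so partition checks are never blurred by rounding.

## The synthetic floodplain

The generator produces the full set of inputs the real study consumes, with
the statistical structure the analysis assumes:

* **Floodwave**: depth
  $D = D_{max}\, s_m \max(0, 1 - d/W_m)^2$ around a meandering permanent
  channel, where $d$ is distance to the channel, $s_m$ a unimodal
  piecewise-cosine seasonal weight (0 in the first month, 1 at the March
  peak) and $W_m = W_{ch}(1 + 40 s_m)$ the monthly inundation half-width.
  Channel cells always hold at least 0.2 m (permanent water). Velocity is
  $0.25\,D$ capped at 0.6 m s^-1^, so floods block mainly by depth, as on
  the real floodplain where velocities stay low. This is a deterministic
  parametric stand-in for a hydrodynamic solver: the access models consume
  only depth/velocity rasters, so the interface is identical. The linear
  capped velocity–depth relation is a fixture convenience, not a physical
  claim.
* **Roads**: one primary road along each valley margin, a lattice of tracks
  crossing the plain with water-crossing segments over the channel, exactly
  one elevated causeway, and secondary spurs to the margin settlements. The
  network is connected in the dry month.
* **Facilities**: 75 facilities — 65 delivery sites, 10 EmOC (7 co-located
  with delivery), 33 MWS — with EmOC hugging the primary roads (urban
  margins) and six delivery sites placed deliberately off-network, mirroring
  rural facilities that lack any road connection.
* **Population**: 8,130 women in 25 clusters, snapped to cell centroids,
  with integer per-point counts produced by largest-remainder rounding so
  the total is exact.

Defaults run on a 200 x 300 grid at 50 m, which keeps a full 13-month
pipeline run under ten seconds on a single core while leaving hundreds of
cells across the floodplain; resolution is a config knob, and the walking
model accepts flood grids coarser than the impedance grid via
nearest-neighbour (never interpolating) resampling, since depth is a
barrier-defining quantity that must not be smoothed across boundaries.

Under these defaults the peak-month flood covers essentially the whole
domain, so peak inaccessibility reaches 100% in the fixture — steeper than
any real floodplain, where high ground persists. What passing tests show is
therefore the *qualitative* floodwave response (unimodal access loss,
worst at the peak month, dry-month optimum) and the exact accounting
identities; they do not calibrate magnitudes against real data. The
zero-amplitude scene keeps the permanent channel, so its water crossings
stay deeply flooded year-round; its "dry baseline" is the pre-flood month,
which the amplitude-0 run reproduces bit-exactly in all 13 months.

## Conventions and degenerate inputs

* Projected metric CRS only; the package never reprojects, and any CRS
  mismatch (or geographic CRS) is an error rather than a silent distortion.
* Cell ownership is half-open, $[x_0, x_0+cs) \times (y_0-cs, y_0]$, row 1
  at the northern edge; the same lookup is used for resampling, point
  sampling and facility placement, which answers the co-registration
  question the source data leave open.
* Rasters are stored as single-band ESRI ASCII grids with a `.prj` sidecar
  (full double precision, explicit nodata); vectors as GeoJSON; facility
  and population tables also as CSV.
* An empty geometry list rasterises to an all-false layer; a month with no
  passable sources yields an all-unreachable surface; out-of-bounds sample
  points produce per-point error entries while the run continues.
* Women are held static across months (no seasonal migration is modelled),
  multimodal transport (canoes, oxen carts) is out of scope, and basic
  versus comprehensive EmOC is not distinguished.

## Known limitations

Travel times are best-case estimates: no care-seeking delays, vehicle
availability, communication failures, road-condition penalties, or fatigue
effects on walking speed. The referral chain models facility-to-facility
transport only (no self-referral or bypassing). The synthetic floodwave has
no hydraulics — no backwater effects, no spatially varying roughness — and a
single channel; it exists to exercise every code path with realistic
structure, not to predict any real floodplain.
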