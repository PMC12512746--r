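---
title: "Movement networks and habitat preference from acoustic telemetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Movement networks and habitat preference from acoustic telemetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reefnet)
library(dplyr)
```

## The analysis

Passive acoustic telemetry records when a tagged animal swims within
listening range of a moored receiver. A detection table — tag id, station
id, timestamp, quality flag — is a sparse, irregular sample of each
animal's path over the receiver array. `reefnet` turns such tables into
directed, weighted *movement networks*: receivers are nodes, and an edge
from receiver A to receiver B aggregates every occasion on which some
individual's consecutive detections moved from A to B. Network metrics then
summarise how animal movement connects habitats: degree centrality flags
core use areas, edge betweenness flags system-wide corridors, and weak
components flag fragmentation. A boosted regression model finally relates
node-level degree to habitat covariates around each receiver, asking which
seascape features predict core use.

The pipeline has five analysis stages, each exported as ordinary functions
that take and return tibbles:

1. **Filtering** (`filter_detections()`): keep QC flags 1–2; drop every
   detection of tags tracked for under 7 days or detected fewer than 50
   times (both thresholds inclusive — a track of exactly 7.0 days or
   exactly 50 detections passes); then suppress repeated detections of a
   tag at one receiver within a 5-minute greedy rolling window. Short,
   sparse tracks are dominated by the tagging site; sub-5-minute repeats at
   one receiver are largely transmission-collision artefacts. Track-minimum
   counts use pre-deduplication detections by default (the counting stage
   precedes the thinning stage); `filter_detections(order =
   "qc_dedup_minimums")` flips this.
2. **Diel classification** (`annotate_periods()`): each detection is
   labelled dawn, day, dusk or night from the solar geometry at its own
   station's coordinates.
3. **Network construction** (`build_stratified_networks()`): movement
   events become aggregated directed edges, stratified per species into a
   full network, four diel-period networks, per-sex networks (F and M
   only), and per-individual networks retained only when they span three or
   more receivers.
4. **Metrics** (`summarize_network()`, `degree_centrality()`,
   `edge_betweenness()`, `common_pathways()`).
5. **Habitat preference** (`assemble_node_covariates()`,
   `assemble_design()`, `fit_habitat_model()`): gradient-boosted regression
   trees of node degree on habitat covariates, with grid tuning, a 75/25
   split and Spearman hold-out evaluation.

`run_pipeline()` executes all stages in order against either CSV inputs or
the built-in simulator, and writes CSV/GraphML/JSON products plus a
manifest that re-checks the pipeline's conservation identities on every
run.

## Edge weights

The weight of an edge pools its movement events as

$$ w = \sum_i \ln\!\frac{1}{\max(\Delta t_i,\ \Delta t_{\min})} $$

where $\Delta t_i$ is the interval (hours) between the two detections of
event $i$. Faster transits contribute more strength, so heavily and
rapidly used links weigh most. Neither the interval unit nor the log base
changes the ordering of weights, only their scale; hours and the natural
log keep typical reef-scale intervals near $\ln 1 = 0$ and both are
arguments (`dt_floor_h`, `log_base`). The floor $\Delta t_{\min}$ defaults
to 5 minutes — the deduplication resolution — so that near-simultaneous
detections at neighbouring receivers cannot produce unbounded weights.

Two receivers occasionally hear the *same* ping, which at second-resolution
timestamps yields two detections of one tag at one instant. Such a pair has
no movement order and would create a zero-length event; event extraction
therefore keeps one detection per (tag, instant), breaking the tie by
station id. This is the one place the pipeline discards a detection outside
the three documented filters.

## Network metrics

*Size* counts aggregated directed edges between distinct receivers;
consecutive detections at one receiver (self-loops) are residency rather
than movement between habitats, so they are bookkept per node and excluded
from size and from degree (a switch re-includes them in degree with
multiplicity two). *Components* are weak components — fragmentation is an
undirected notion. Degree obeys the handshake identity
$\sum_v d(v) = 2\times\text{size}$, which the pipeline manifest re-checks
on every run.

Edge betweenness needs a positive length per edge, and the log-inverse-time
weights can be negative. The default length is `1/event_count`, preserving
"stronger = shorter"; `unit` and `inverse_weight` modes are exposed, the
latter rejected whenever any weight is non-positive. Ties among
equal-length shortest paths are split fractionally (Brandes accumulation),
never by arbitrary path choice. The implementation is backed by igraph and
is tested against an exhaustive path-enumeration oracle on random digraphs.

*Common pathways* are edges shared by two or more species' networks whose
betweenness is high — at or above the 0.75 quantile of positive values —
within **every** species sharing the edge. The quantile is an argument; no
single threshold is canonical, and the upper quartile is a conservative
default. Betweenness is min–max scaled within each network for display
parity across species of very different network sizes.

## Solar classification

Diel periods follow the suncalc event conventions: night below −18°
altitude (astronomical night), sunset at −0.833° (refraction plus solar
radius), end of the morning golden hour at +6°. Classification is
instantaneous — from altitude and its sign of change — which is provably
equivalent, at tropical and temperate latitudes, to interval membership
between the four daily event times, and avoids any timezone handling:
computing solar geometry at the station's coordinates reproduces local time
implicitly. The solar position kernel implements the NOAA low-precision
ephemeris (accuracy well under 0.3°); event times are root-bracketed to
below one second. On high-latitude degenerate days a threshold may never be
crossed: the rule set remains total (classification degrades to an
altitude-plus-trend rule) and `solar_event_times()` reports the missing
events as `NA`. The package's test latitudes are tropical; polar behaviour
is documented, not warranted.

## The habitat model

One design row is a (individual network, diel period, receiver) triple: the
response is the node's degree in that individual's period-specific network;
predictors are habitat-class proportions within 300 m of the receiver,
depth, distance to the nearest reef crest, distance to the main crest
passage, the individual's sex, and the period (`tod`). Stacking by period
is the default; `assemble_design(stack_by_period = FALSE)` instead uses the
full-network degree with no `tod` term, which is the appropriate design
when diel structure is not under study — with stacking, `tod` always
carries the mechanical signal that dawn and dusk are ~1-hour windows while
day and night are ~11-hour windows.

The learner is stochastic gradient-boosted regression trees via xgboost
(squared-error boosting; interaction depth = max tree depth, bagging
fraction = row subsample, shrinkage = learning rate). The module owns the
protocol: a seeded 75/25 split, grid tuning over every candidate setting by
5-fold cross-validated RMSE (with the best iteration within each setting's
tree cap), relative influence as the normalised loss-reduction attribution
(dummy columns of a categorical predictor pooled back to the predictor,
summing to 100), and Spearman rank correlation between predictions and
observations on the hold-out. Constant predictions make the correlation
undefined; that is signalled (`NA` plus a warning), never silently zeroed.
Both a train R² and the hold-out Spearman are reported; no claim is made
that either matches any particular field dataset.

## Habitat covariates

The habitat scene is a planar matrix bundle — class grid, depth grid, crest
mask, passage cells — at a common placement, 50 m cells by default.
Stations and cells live in a local metric plane: at atoll scale (tens of
km) planar distances differ negligibly from geodesics, and the synthetic
scenes are generated directly in metres. Proportions within the 300 m
sampling radius are computed by cell-centre-in-disc counting (unbiased when
the radius is several cells wide); cells beyond the grid edge are dropped
and proportions renormalised, with the covered fraction reported. Depth is
sampled bilinearly; habitat class nearest-neighbour (it is categorical).
Feature distances are exact nearest-cell-centre distances, zero when the
station sits on the feature.

## What the simulator emulates — and what it does not

The synthetic module generates the study conditions the pipeline assumes:
one or more atolls, each a lagoon (sand with coral patches) ringed by an
emergent reef crest broken by passages, with a forereef apron; receivers in
the lagoon, at each passage mouth (one just inside, one just outside) and
around the forereef; and tagged animals as biased correlated random walks
with site fidelity (attraction to a home centre), diel activity
multipliers, sex-specific ranging, and occasional inter-atoll excursions
that head for the destination atoll's passage mouth. The crest ring is a
reflecting barrier, so lagoon–forereef exchange must use the passages —
which is what makes passages emerge as high-degree nodes. Detection is a
logistic function of distance with 50% probability at 300 m (the receiver
range estimate), independent across pings and receivers. Transmitters ping
at ~90 s with uniform jitter; QC flags are drawn with a small contamination
rate so the QC filter has work to do.

Default scale — up to ~16 animals, 12–30 days, 60 s steps, one or two
atolls — keeps a full pipeline run in seconds and the whole validation
suite in minutes while leaving hundreds of movement events per network.
The vignette states these sizes as the package's chosen study conditions;
the seeded-recovery checks (passage stations in top-3 degree;
suppressed-dawn activity giving the smallest dawn network; wider-ranging
females giving larger female networks with inter-atoll edges;
channel-proximate home placement making `dist_channel` the top GBM
influence) are run across 20 seeds each.

Passing those checks shows the pipeline recovers structure *that the
generator planted*. Real telemetry adds much the simulator omits: tag
collisions and close-proximity detection interference beyond simple
thinning, receiver outages and clock drift, tides, currents, lunar and
thermal drivers of movement, behavioural states beyond a single
home-attracted walk, and detection ranges that vary with sea state. Results
on real arrays depend on those processes; the tests here validate the
computation, not the ecology.

## Numerical and degenerate-input choices

- All timestamps are stored and compared in UTC; readers accept any
  ISO-8601 offset.
- Deduplication is a greedy rolling window anchored on the last *kept*
  detection — idempotent, unlike fixed binning.
- Sorting by (tag, timestamp, station) makes every product invariant to
  input row order; rerunning `run_pipeline()` with one config and seed
  reproduces every output byte-for-byte (xgboost is pinned to one thread
  and its internal RNG seeded).
- Empty strata are empty networks, not errors; an all-filtered detection
  table completes the pipeline with warnings.
- Single-level factors in a design table (e.g. one-sex species) are
  dropped from the model matrix and reported with zero influence rather
  than breaking contrasts.
- The simulator fans a single top-level seed into independent substreams
  (scene, agents, tracks, detections) so stages can be regenerated
  independently.

## Known limitations

- Betweenness magnitudes depend on the chosen edge-length transform; when
  comparing against other software, match `length_mode` first.
- The 3-node rule is applied at the node level; an individual shuttling
  between two receivers, however intensely, contributes no individual
  network.
- The planar approximation and the cell-centre disc rule are inappropriate
  for scenes spanning hundreds of kilometres or radii comparable to one
  cell.
- `read_detections()` assumes per-deployment unique tag ids; re-used tags
  across deployments must be disambiguated upstream.
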