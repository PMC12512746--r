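# reefnet

Movement networks and habitat preference from passive acoustic telemetry on
coral reefs.

Arrays of moored acoustic receivers log every time a tagged animal
(reef sharks, large reef fish) swims within listening range (~300 m). This
package turns those detection logs into **directed, weighted movement
networks** — receivers as nodes, consecutive detections of an individual as
edges — and uses network metrics and boosted habitat models to quantify how
predator movement creates seascape connectivity within and between reef
atolls. It is aimed at movement ecologists working with telemetry
databases who want a tested, reproducible version of this analysis, plus a
synthetic atoll simulator so every stage can be validated without field
data.

## The method

For each species, filtered detections (QC flags 1–2; tracks of ≥ 7 days
and ≥ 50 detections; 5-min per-receiver deduplication) are converted into
movement events — consecutive detections of one individual from receiver
*A* to receiver *B* (self-loops when *A* = *B*). Events aggregate into
edges weighted by

&nbsp;&nbsp;&nbsp;&nbsp;*w* = Σᵢ ln( 1 / max(Δtᵢ, Δt_min) )

so movements with shorter inter-detection times Δt carry greater strength.
Networks are stratified: full, per diel period (dawn/day/dusk/night from
solar altitude at each station: night below −18°, sunset at −0.833°,
golden-hour end at +6°), per sex, and per individual (kept when spanning
≥ 3 receivers). Metrics per network: order, size, weak components, node
degree *d* (in+out edges, self-loops excluded; Σd = 2·size), edge
betweenness *b* (fraction of all-pairs shortest paths through each edge),
and cross-species *common pathways* (shared edges with jointly high *b*).
Node degree from individual networks is then modelled on habitat covariates
(class proportions within 300 m, depth, distance to reef crest, distance to
the crest passage, sex, time of day) with gradient-boosted regression
trees: 75/25 split, grid tuning by cross-validated RMSE, relative influence
normalised to 100%, Spearman evaluation on the hold-out.

## Worked example

```r
library(reefnet)
library(dplyr)

sim <- simulate_telemetry(seed = 7, duration_days = 14)   # synthetic atoll study
det <- left_join(sim$detections, select(sim$tags, tag_id, species, sex),
                 by = "tag_id")
annotated <- annotate_periods(filter_detections(det), sim$stations)
nets <- build_stratified_networks(annotated, sim$tags, sim$stations)

full <- nets$network[[which(nets$species == "grey_reef_shark" &
                            nets$stratum_type == "full")]]
full
#> <movement_network> species=grey_reef_shark, sex=all, period=all, tag_id=all
#>   order 5, size 15, components 1, self-loop events 14256
head(degree_centrality(full), 3)
#>   station_id degree
#> 1 ST02            8
#> 2 ST01            6
#> 3 ST06            6
head(edge_betweenness(full), 3)
#>   from  to    event_count weight betweenness
#> 1 ST01  ST02          405  800.            6
#> 2 ST01  ST05           43   96.7           4
#> 3 ST01  ST06           89  166.            0
```

The sharks in this simulated study are homed near the reef-crest passage,
and the two passage-mouth receivers (ST01, ST02) duly emerge as the
highest-degree core-use nodes, linked by the strongest, highest-betweenness
edge (405 movement events). The habitat model recovers the same structure
from covariates:

```r
cov <- assemble_node_covariates(sim$scene, sim$stations)
des <- assemble_design(annotated, sim$tags, cov, species = "grey_reef_shark")
fit <- fit_habitat_model(select(des, -tag_id, -station_id), seed = 7,
                         grid = settings_grid(c(1L, 3L), 0.1, 0.75, 300L))
fit
#> <habitat_gbm> degree ~ tod + sex + prop_coral + ... + dist_channel_m
#>   depth 3, shrinkage 0.1, bag 0.75, trees 39 | R2(train) 0.763, rho(test) 0.732
#>   top influence: tod (51.2%), dist_channel_m (20.4%), sex (10.3%)
```

Time of day and distance to the passage dominate: degree is highest in the
long day/night periods and at passage-adjacent receivers, and the hold-out
Spearman correlation of 0.73 says the fitted model ranks unseen
station-periods accurately. `autoplot(full)`, `autoplot(fit)` and
`autoplot(sim$scene, sim$stations)` draw the network map, the influence
chart and the habitat scene; `tidy()`/`glance()` return every result as a
tibble. `run_pipeline(list(seed = 7), out_dir = "out")` executes all of the
above plus exports (CSV, GraphML, JSON manifest) in one call.

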