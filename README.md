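# nutrisom

Movement and co-occurrence analysis of radio-tracked, semi-aquatic
mammals with a geographically tolerant self-organizing map (Geo-SOM).
The motivating system is an invasive nutria (*Myocastor coypus*)
population radio-tracked monthly in a narrow wetland corridor; the
package is for movement ecologists who want to relate where animals
go, how close they get to one another, and which habitats host those
encounters.

## What it computes

Starting from a fix table (one row per radio-tracking observation), a
labelled habitat map and a monthly water-temperature table, the
pipeline derives:

* **Movement parameters** — per-step linear speed (LiS, m/h), compass
  bearing, turning angle and angular speed (AnS, deg/h), with
  log-spaced speed histograms and circular orientation counts.
* **Nearest-neighbour distances** — for each animal at each
  time-matched snapshot: the distance to its nearest neighbour of any
  sex (DAS), of the same sex (DSS) and of the different sex (DDS),
  with `das = min(dss, dds)` by construction, sparse missingness
  imputed by individual means (only below a 5% missing fraction), and
  sex-specific eligibility thresholds.
* **Dyadic co-occurrence** — every pair of animals within a radius at
  a snapshot is one event, classed F-F / F-M / M-M; radii are swept
  from 50 to 2000 m, monthly class frequencies are profiled, and a
  support-persistence rule picks the largest radius at which the
  pattern seen at the base radius is unchanged.
* **Geo-SOM** — a from-scratch SOM over named variables
  (location X/Y, water temperature WT, eight habitat indicators,
  LiS/AnS, and either the three distances or the three co-occurrence
  incidences). Each node computes the summed squared distance
  `d_j = sum_i (x_i - w_ij)^2`; the BMU search first finds the node
  nearest in the geographic components alone, then searches the full
  distance within lattice radius `k` (geographic tolerance, default 3)
  of that geo-winner; updates are bubble-neighbourhood,
  `w <- w + eta * (x - w)` for nodes within the shrinking radius.
  Training is rough (200 iterations, radius 4, rate 0.2) then fine
  (20 iterations, radius 10, rate 0.1) on a 9 x 6 map.
* **Codebook analysis** — k-means over the node weights with
  Davies-Bouldin selection of the cluster count, per-cluster distance
  statistics, pairwise Welch t-tests with Holm correction, a sex-ratio
  plane (+1 female, -1 male; normalised 0.5 = parity), and
  plane-association scores (Spearman correlation, extremum overlap,
  and enrichment of a habitat plane in an incidence plane's high
  region) replacing visual matching of component maps.

Because the original study's raw fixes are not deposited, the package
also ships a seeded synthetic telemetry generator
(`reference_dataset()`) reproducing the study design — 24 animals
(12 F / 12 M), 12 monthly 3-day survey rounds at 1–2 h fix intervals,
heavy-tailed speeds calibrated to the published moments, home ranges,
territorial avoidance, and plantable sex-pair/habitat associations —
so the whole pipeline is testable end to end and planted effects can
be recovered.

## Worked example

```r
library(nutrisom)

ds  <- reference_dataset()   # fixes, habitat map, temperatures, truth
res <- run_pipeline(ds$fixes, ds$map, ds$temps, pipeline_config(seed = 1))
print(res)
#> pipeline_result
#>   fixes: 13314 (24 individuals), snapshots: 864
#>   mean speed 53.8 m/h (SD 80.7), stable radius 50 m, 3408 events
#>   codebook clusters: k = 5

head(res$association$ranks$FM, 4)
#>   variable enrichment  score polarity extremum_overlap
#> 1       TG      2.179  0.584    match              0.2
#> 2       OA      1.079 -0.149  inverse              0.2
#> 3        R      0.967  0.151    match              0.0
#> 4      HHV      0.899  0.025    match              0.0
```

The mean speed and SD sit inside the calibration band around the
published 48.3 ± 96.2 m/h. The F-M incidence plane is most enriched in
tall grassland (TG, enrichment 2.18 — the high-incidence region holds
2.2 times the map-average TG weight), which is exactly the association
the reference simulation plants; the same ranking recovers
floating-leaved hydrophytes (FL) for both same-sex planes. Five
codebook clusters are selected by Davies-Bouldin. The analytic
sex-ratio check `sex_ratio(c("F","F","M","M"))$sr_norm` returns 0.5
exactly.

`write_pipeline_outputs(res, "outputs")` writes the manifest and all
per-stage CSVs (steps, neighbour records, profiles, events, component
planes, clusters, statistics, association tables); re-running with the
same inputs and seed reproduces them byte for byte.

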