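# sealforage

Fine-scale foraging analysis for diving marine predators carrying
head-mounted sonar/motion tags (developed around lactating Weddell seal
deployments, applicable to any biting predator tagged the same way). The
package turns raw multi-rate tag channels — triaxial acceleration at
200/250 Hz, magnetometry and depth at 50 Hz, GPS fixes, and 25 Hz
micro-sonar echograms over a 7 m range — into the quantities a foraging
study reports, and ships a fully labelled synthetic-deployment simulator so
the whole chain can be validated without field data.

## What it computes

* **Prey capture attempts (PrCAs)** from triaxial jerk: the jerk magnitude
  `j[k] = fs · ‖a[k+1] − a[k]‖` (m/s³) is summarised by a sliding RMS;
  events are maximal runs above 150 m/s³, merged across silent gaps
  shorter than 5 s, then filtered to a 5 s minimum duration. Events get
  depth and dive context; a survival curve of inter-event gaps diagnoses
  the merge threshold.
* **Dives and day periods**: segmentation at the 5 m depth threshold
  (shallow under-ice activity kept separately), 40 m depth-bin counts, and
  day/twilight/night labels from a self-contained solar-elevation routine
  (twilight = [−12°, 0°]).
* **Echogram prey interactions** in ±5 s windows around each attempt:
  echo-to-noise-ratio images, seafloor-line detection (benthic
  classification), connected-component prey-trace extraction, single vs
  schooling echoes, reaction classification (*leave seafloor* = straight
  negative-slope trace departing the ridge; *escape* = curved
  down-then-up trace clear of the floor), reaction distance and onset
  time, and acoustic size (supra-threshold pixel extent per ping column).
* **Dive-shape clusters**: profiles normalized to 101 points and z-scored,
  functional PCA on a cubic B-spline basis, Gaussian-mixture clustering
  (EM over K = 1..9 and six covariance families, BIC selection) with an
  80% posterior assignment rule, cluster envelopes and per-cluster PrCA
  tallies.
* **Approach behaviour**: pitch/roll/heading from accelerometer +
  tilt-compensated magnetometer, dead-reckoned local tracks with a
  depth-rate speed model, band-passed flipper-stroke counts, head-turn
  direction within ±1 s of the prey reaction, and per-reaction-type
  summary tables over the −10 s…+5 s approach window.
* **Deployment reports**: per-individual and pooled tables (counts, time
  budgets, depth/duration statistics, benthic and prey-trace percentages,
  GPS daily radius).

## Worked example

```r
library(sealforage)

cfg <- sim_config(n_individuals = 2, n_dives = c(8, 6),
                  n_foraging_dives = c(3, 2), n_prca_total = c(9, 5))
dep  <- simulate_deployment(cfg, seed = 42)
proc <- process_deployment(dep)   # segment dives, detect PrCAs, read echograms
build_reports(proc)[, c("individual", "n_dives", "n_prca",
                        "n_dives_with_prca", "pct_dives_with_prca",
                        "prca_depth_mean", "n_benthic", "n_traces")]
#>   individual n_dives n_prca n_dives_with_prca pct_dives_with_prca prca_depth_mean n_benthic n_traces
#> 1          1       8      9                 3               37.50        88.20078         8        3
#> 2          2       6      5                 2               33.33        91.95384         5        2
#> 3      total      14     14                 5               35.71        89.54116        13        5
```

All 14 injected capture attempts are recovered, at a pooled mean depth of
89.5 m against the configured 88 ± 30 m capture-depth distribution; 13 of
the 14 echogram windows show the seafloor (the configured benthic rate is
98%), and 5 carry a prey trace. The prey summary pools the per-window
echogram reads:

```r
summarize_prey(proc$prey)
#> (total row)  n_prca 14, n_traces 5, n_reactive 3 (1 leaving the seafloor,
#>              2 escaping), mean reaction distance 63.2 cm, acoustic size 5 cm
```

Dive-shape clustering runs on the segmented profiles:

```r
shapes <- cluster_dive_shapes(proc$segs)        # fPCA + mixture + 80% rule
summarize_clusters(shapes$assignment, shapes$curves,
                   data.frame(id = shapes$keep[, "dive"],
                              individual = shapes$keep[, "individual"]))
```

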