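# rangeselect

Home-range estimator selection for animal telemetry by area-under-the-curve
(AUC) goodness of fit.

Wildlife researchers estimating a home range from GPS or VHF relocations
must pick one estimator from a crowded field, and the traditional choice —
a kernel density estimator justified by old simulation studies — is often a
poor fit for modern GPS datasets with thousands of autocorrelated fixes.
`rangeselect` implements eight estimators spanning three generations and a
single relative metric for choosing among them on *your* dataset:

* **Hull-based (first generation):** minimum convex polygon (`mcp`,
  building block), k-nearest-neighbour local convex hulls (`locoh`,
  k = √n), single-linkage cluster analysis (`slca`), characteristic hull
  from ordered Delaunay triangles (`char`).
* **Kernel-based (first/second generation):** fixed KDE with the reference
  bandwidth h = √((s²ₓ+s²ᵧ)/2)·n^(−1/6) (`lkde`), bivariate plug-in
  bandwidth matrix (`pkde`), least-squares cross-validation with declared
  failure on duplicate-heavy data (`lscv`).
* **Movement-based (third generation):** Brownian bridge movement model
  (`bbmm`), dynamic BBMM with a sliding-window motion variance (`dbbmm`),
  and a biased-random-bridge movement kernel (`mkde`).

Every estimator is rasterized onto one fixed-grain reference grid per
animal (100 × 100 m by default). The AUC then treats each grid cell as an
observation — response 1 if the cell holds a relocation, predictor the
cell's score — and computes the tie-corrected rank-sum statistic

    AUC = (#{presence > absence pairs} + ½·#{tied pairs}) / (n₁·n₀),

the area under the ROC curve: 0.5 is no discrimination, 1.0 a perfect fit
of the isopleths to the relocations. The package also ships the
downstream comparison (Kruskal–Wallis and Bonferroni pairwise tests,
random-intercept mixed models on logit-AUC fitted by profiled likelihood,
AICc model selection over the 12-model candidate set) and a seedable
simulator of home-ranging movement (Ornstein–Uhlenbeck) under GPS duty
cycles (74% fix success, 34 m error) and VHF flight schedules
(Mon/Wed/Fri mornings, 124 m error), so the full pipeline runs with no
field data.

## A worked example

Simulate one animal for 60 days, observe it on an hourly GPS duty cycle,
and fit a Brownian bridge home range:

```r
library(rangeselect)
prm  <- ou_params(duration_days = 60)        # 3 km stationary SD, 1/day reversion
path <- simulate_ou(prm, seed = 7)
tr   <- observe_gps(path, "hourly", seed = 8, animal_id = "F101")
tr
#> <hr_trajectory> animal F101: 1069 fixes over 60.0 days (GPS, hourly)

hr <- homerange(tr, "bbmm")
hr
#> <homerange> bbmm for animal F101 (1069 fixes, GPS)
#>   AUC = 0.8802
#>    50.0% isopleth: 31.45 km^2
#>    95.0% isopleth: 118.72 km^2
#>   100.0% isopleth: 295.00 km^2
```

The animal kept 1069 of 1441 hourly attempts (the 74% fix success), the
fitted Brownian motion variance is ~230 m²/s, and the 95% isopleth — the
smallest region holding 95% of the utilization distribution — covers about
119 km², panther-scale. `plot(hr)` draws the surface, fixes and contours;
`write_ascii_grid()` / `write_isopleths_geojson()` export them for GIS.

Scoring all eight estimators on the same reference grid:

```r
tab <- auc_table(list(tr))
tab[, c("estimator", "auc")]
#>   estimator    auc
#> 1     locoh 0.8671
#> 2      slca 0.8848
#> 3      char 0.8954
#> 4      lkde 0.8628
#> 5      pkde 0.8636
#> 6      bbmm 0.8802
#> 7     dbbmm 0.8835
#> 8      mkde 0.8832
```

The movement-aware estimators and the concave-hull family outrank the
location-only kernels for this fast, autocorrelated schedule; a kernel
smooths over the gaps the animal never used. `run_comparison(tab)` on a
multi-animal table adds the Kruskal–Wallis test, pairwise comparisons, the
mean ± SE summary per technology × estimator, and AICc selection over the
12 candidate mixed models of logit-AUC.

A thin command-line wrapper is included for shell pipelines:

```sh
Rscript inst/cli/rangeselect.R simulate --animals 10 --days 365 --seed 42 --out sims
Rscript inst/cli/rangeselect.R estimate --estimator bbmm --in sims/locations_gps.csv --out-dir rasters
Rscript inst/cli/rangeselect.R auc --locs sims/locations_gps.csv --out auc.csv
Rscript inst/cli/rangeselect.R compare --auc auc.csv --out report
```

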