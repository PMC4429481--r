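---
title: "Selecting a home-range estimator by area-under-the-curve"
author: "rangeselect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting a home-range estimator by area-under-the-curve}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

A home range summarizes the area an animal uses during its normal
activities. Modern GPS collars deliver thousands of autocorrelated
relocations per animal per year, while concurrent VHF aerial telemetry of
the same animals yields around a hundred sparse, noisier fixes. Home-range
estimators differ enormously in how they turn such relocations into a
utilization distribution (UD) — a probability surface whose volume contours
(isopleths) are the home-range boundaries — and no single estimator is best
for every dataset. `rangeselect` implements a suite of eight estimators
spanning three generations, a goodness-of-fit statistic (AUC) that measures
how well each estimator's isopleths fit the relocations on a common
reference grid, and the downstream statistical comparison (rank tests,
logit-AUC mixed models, AICc model selection). A seedable movement and
observation simulator lets the whole pipeline run, and be tested, without
field data.

# The AUC statistic

All surfaces are evaluated on one reference grid per animal (100 m grain by
default, identical extent across estimators, since AUC is scale-dependent).
Each grid cell becomes one observation: the response is 1 when the cell
contains at least one relocation and 0 otherwise, and the predictor is the
estimator's cell score. The AUC is the tie-corrected rank-sum statistic

$$\mathrm{AUC} = \frac{\#\{\text{pairs with presence cell scored higher}\}
 + \tfrac12\,\#\{\text{tied pairs}\}}{n_1 n_0},$$

which equals the trapezoidal area under the ROC curve. A constant surface
scores 0.5 (no discrimination); 1.0 means every occupied cell outranks
every empty cell. Two properties matter for interpretation:

* AUC is invariant under strictly increasing transforms of the scores, so
  only the *ranking* of cells matters — hull estimators can compete with
  probabilistic UDs, and a kernel estimator is not rewarded or punished for
  a pure rescaling of its bandwidth, only for ranking cells differently.
* Presence is binary per cell: a cell holding ten fixes counts once.
  Multiplicity still influences the comparison through the estimators
  themselves, which concentrate score where fixes accumulate.

Cells a hull estimator never covers carry a score of `-Inf`, ranking below
every covered cell, which is exactly how an isopleth that misses
relocations should be penalized.

# The estimator suite

**First generation (geometry and plain kernels).**

* `mcp` — minimum convex polygon (building block, not part of the
  comparison suite).
* `locoh` — k-nearest-neighbour local convex hulls: one hull per point
  (with its $k-1$ nearest neighbours, $k=\sqrt n$ rounded, minimum 3),
  sorted by area and progressively unioned; a cell's level is the
  percent-of-points covered when the union first reaches it.
* `slca` — single-linkage cluster analysis. The process seeds with the
  tightest 3-point triple and then repeatedly takes the cheapest of three
  moves: attach the closest unassigned point to a cluster (single-linkage
  distance), open a new 3-point cluster (a point with its two nearest
  unassigned neighbours, mean pairwise distance), or merge the two closest
  clusters. Isopleths are unions of per-cluster convex hulls over the first
  $\lceil P\% \cdot n\rceil$ assigned points. The published description of
  this method specifies the seed and the stopping rule but not the exact
  step priority; the rule above is this package's concretization, chosen to
  be deterministic (ties break attach < new < merge, then lowest index) and
  is frozen by a step-by-step oracle in the test suite.
* `char` — characteristic hull: Delaunay triangles ordered smallest to
  largest; the P% isopleth is the shortest prefix of triangles holding at
  least P% of the points. With no triangles removed the region is exactly
  the minimum convex polygon, a limit the tests assert to machine
  precision on random point sets.
* `lkde` — fixed kernel density with the reference bandwidth
  $h = \sqrt{(s_x^2+s_y^2)/2}\; n^{-1/6}$.

**Second generation.** `pkde` — kernel density with a full bivariate
plug-in bandwidth matrix: the data are sphered, sixth-order density
derivative functionals are taken at their normal-reference values, a single
pilot $g = (16/(3n))^{1/8}$ (the AMSE-optimal pilot for the three
even fourth-order functionals, which coincide under the normal reference)
is used to estimate all five $\psi_{\mathbf r},\ |\mathbf r| = 4$
functionals by kernel sums, and the asymptotic MISE

$$\mathrm{AMISE}(H) = \frac{|H|^{-1/2}}{4\pi n}
 + \frac14\!\int\!\big(\mathrm{tr}\,H\,\nabla^2\hat f\big)^2
 = \frac{|H|^{-1/2}}{4\pi n} + \frac14\,
   \mathbf h^\top \hat\Psi_4\, \mathbf h,
 \qquad \mathbf h = (h_{11}, h_{22}, h_{12}),$$

is minimized over symmetric positive-definite matrices through a
log-Cholesky parameterization with a deterministic quasi-Newton start at
the normal reference. `lscv` — least-squares cross-validation, provided as
the classical VHF-era fallback: the score is minimized over a bracketed
scalar range ($[g/100,\ 10\,h_{\mathrm{ref}}]$ with $g$ the grid grain);
when the minimum sits at the lower bracket edge — which duplicated
locations force, since the leave-one-out term then diverges as
$h \to 0$ — the selector *declares failure* rather than returning a
degenerate bandwidth.

**Third generation (time, error and movement).**

* `bbmm` — Brownian bridge movement model. The motion variance
  $\sigma^2_m$ (m²/s) is fitted by the leave-one-out construction:
  odd-indexed fixes define bridges and each even-indexed fix at relative
  time $\alpha$ of its bracketing gap $T$ is scored under a bivariate
  normal centered on the linear interpolation with per-axis variance
  $T\alpha(1-\alpha)\sigma^2_m + \delta_e^2 + (1-\alpha)^2\delta_1^2 +
  \alpha^2\delta_2^2$. The $\delta_e^2$ term is the location error of the
  scored fix itself: every fix is observed with error, and omitting this
  term would inflate $\hat\sigma^2_m$ by $\delta^2/(T\alpha(1-\alpha))$ —
  with hourly fixes and 30 m error that is a three-fold bias, which the
  parameter-recovery tests would catch immediately. The UD averages the
  bridge density over interior $\alpha$ values (midpoint rule; the default
  10 steps per segment is within $10^{-4}$ total variation of a 10× finer
  quadrature on the tested tracks), weighting segments by duration.
* `dbbmm` — dynamic BBMM: a 31-fix window slides along the path; within
  each window a single-variance model competes by BIC
  ($-2\ell + k\ln m$, $m$ = scored bridges) against two-variance models
  split at each interior breakpoint at least 11 fixes from the window
  edges. Each fix receives the average selected-model variance over the
  windows covering it; trajectory margins inherit the nearest interior
  value. Window 31 and margin 11 follow the method's source defaults. Note
  the noise floor this implies: a 31-fix window scores only ~15 bridges,
  so individual windowed estimates scatter with roughly 25% relative
  error even on a perfectly homogeneous track. The tests therefore assert
  that windowed variances *center* on the global estimate and that the
  two-phase behavioral change is detected, not that every fix sits within
  a band tighter than the sampling noise allows. With a constant variance
  sequence the dBBMM surface reduces to the BBMM surface exactly.
* `mkde` — movement-based kernel density estimation by biased random
  bridges: segments no longer than `tmax` (12 h default) are interpolated
  every `tau` seconds (300 s default) and each interpolated point carries
  a normal kernel with $h^2(p) = h_{\min}^2 + 2p(1-p)DT$ — pinned to
  $h_{\min}$ (34 m default, the GPS error scale) at the fixes and maximally
  inflated mid-segment. $D$ is the method-of-moments diffusion
  $\hat D = \overline{d^2/(4T)}$ unless supplied. The factor
  $2p(1-p)DT$ matches the Brownian-bridge variance shape; it is isolated in
  one expression so the scale constant can be revised if a different
  convention is preferred. Segments shorter than `lmin` (50 m) are treated
  as stationary. When *no* segment fits under `tmax` — the VHF situation,
  with days between fixes — the estimator raises an error rather than
  returning a meaningless surface, and the AUC table records the failure
  as a missing value.

# The statistical comparison

`auc_table()` produces one record per animal × estimator with the
covariates the comparison uses: location count (binned `<100`, `101–500`,
`501–1000`, `>1000`; counts of exactly 100 fall in the first bin per the
printed labels), fix success, collection schedule (`hourly` ≤ 1 h, `four`
2–4 h, `seven` 7–14 h, `vhf`), study area, technology.

`run_comparison()` then reproduces the analysis pipeline:

1. Kruskal–Wallis rank test over technology × estimator groups (15 groups
   when VHF cannot support the movement-based KDE, hence df = 14), and
   Bonferroni-adjusted pairwise Welch t-tests.
2. A mean ± SE AUC summary per group.
3. AICc selection over the 12 a-priori random-intercept models of
   logit-AUC on the GPS records. AUC values of exactly 1 (possible for
   hull estimators on small grids) are clamped to $1 - 1/(2\,n_{\mathrm
   cells})$ with a warning so the logit stays finite without discarding
   records.

The mixed model $y = X\beta + b_{\mathrm{animal}} + e$ is fitted by
profiling the likelihood over $\lambda = \sigma_a^2/\sigma_e^2$: for fixed
$\lambda$ the GLS estimates and $\hat\sigma_e^2$ have closed forms through
per-group sums, leaving a one-dimensional optimization with the
$\lambda = 0$ boundary checked explicitly (where the fit reduces to
ordinary least squares). The SLCA estimator is the reference level.
Coefficient tables are REML; *model selection uses maximum likelihood*,
because REML likelihoods are not comparable between models with different
fixed effects and the 12 candidate models differ exactly there. `K` counts
fixed effects plus two variance parameters; this convention is reported
as-is and not forced to match any particular published parameter count.
The fit is cross-checked against an independent mixed-model implementation
in the test suite; AICc is
$-2\ell + 2K + 2K(K+1)/(n-K-1)$ and Akaike weights
$w_i = e^{-\Delta_i/2}/\sum_j e^{-\Delta_j/2}$, with models flagged as
candidates when $\Delta_i < 4$.

# The simulator

Real relocations of the study system this framework was built around are
not publicly deposited, so the package ships a generator that emulates the
observation processes instead; everything downstream is tested against it.

**Movement** is an Ornstein–Uhlenbeck process per axis, simulated with the
exact transition
$X_{t+\Delta} = \mu + e^{-\beta\Delta}(X_t-\mu) +
\mathcal N\!\big(0,\ \tfrac{\sigma^2}{2\beta}(1-e^{-2\beta\Delta})\big)$,
started from the stationary law. OU is the simplest process with a true
long-run home range (stationary and mean-reverting), which is what the
estimators are supposed to recover; it is a stand-in, not a claim about
panther behavior. Defaults: stationary SD 3 km (a range spanning roughly
10–15 km) and reversion time scale $1/\beta$ = 1 day. The time scale
deserves a note: with a much faster reversion (hours) and the same 3 km
range, hourly displacements approach 1.6 km — about 40 km of travel per
day, implausibly fast for a large terrestrial carnivore — and hourly GPS
sampling can no longer resolve movement, which flattens the distinction
between movement-aware and location-only estimators that the framework is
designed to expose. At $1/\beta$ = 1 day the hourly steps are 600–850 m
(~15 km/day), within reported movement rates for large cats. A two-state
variant switches OU parameters mid-path (continuously) as the fixture for
windowed-variance tests.

**GPS observation** samples the path on the duty cycle (hourly / 4 h /
7 h), drops each attempt independently with probability $1 - 0.74$ (the
emulated overall fix success), and adds N(0, 34² m²) error per axis, with
the error SD recorded per fix. **VHF observation** flies Monday, Wednesday
and Friday at a uniform time in the 0700–1100 window, locates the animal on
a given flight with probability 0.67, and adds N(0, 124² m²) error. The
flight-success probability reconciles the 3-per-week schedule (156
potential fixes/yr) with the ~105 ± 29 locations/yr regime typical of
aerial VHF monitoring — cancelled flights and failures to home in on the
beacon are the physical mechanism. Changing only an error SD leaves
timestamps and dropout untouched (the RNG stream order is fixed), which
the reproducibility tests rely on.

**The benchmark cohort** (`make_benchmark_cohort`) simulates independent
animals each observed under both technologies, with per-animal seeds
derived from one master seed and the OU truth stored for recovery tests.
The packaged comparison study uses 10 animals over a 120-day span (about
2,100 GPS and 35 VHF fixes per animal) — large enough that every estimator
runs in its intended regime, small enough that the full 8-estimator × 2-
technology comparison completes in a few minutes. The generator's default
span remains 365 days, which reproduces the annual VHF location regime.

What passing tests on this cohort do and do not show: the simulator has no
habitat, no hard range boundaries, no diel activity cycle, no
collar-specific fix-success differences, and movement is a single
stationary Gaussian process. Estimator *orderings* that depend only on
sampling rate, location error and autocorrelation (GPS > VHF; bridge-based
above location-only on fast schedules) transfer; absolute AUC values and
habitat-driven effects do not.

# Numerical choices and degenerate inputs

* **Grid.** Origin snapped down to a multiple of the grain; buffer default
  3 grains per side; off-grid kernel mass above 0.1% triggers a warning.
  Cells are half-open in both axes (points on the maximum edge belong to
  the last cell), so every in-extent point maps to exactly one cell.
* **Volume contours.** Equal-mass cells share one level (the accumulated
  mass at the end of their tie group); zero-mass cells get level `Inf` so
  the 100% isopleth is exactly the positive-mass region.
* **Delaunay.** Bowyer–Watson with determinant (orientation/in-circle)
  predicates on unit-box-scaled coordinates; zero-area slivers are kept so
  the triangulation stays a tiling, and a boundary-repair pass ear-fills
  any hull notch left by floating-point conflict decisions — the
  characteristic hull's 100%-region-equals-MCP identity then holds to
  machine precision, which the tests assert on hundreds of random sets.
* **Duplicate points.** Retained by the hull estimators (duplicate-heavy
  GPS data are the motivating case): degenerate LoCoH hulls have zero area
  and sort first; the triangulation collapses duplicates and counts them
  through their representative.
* **Bridge likelihoods.** Variance floors at $10^{-12}$–$10^{-9}$ m²
  guard zero-error zero-variance corners; the σ² optimizer is a bracketed
  golden-section search with the upper bracket derived from the largest
  single-bridge MLE; boundary estimates at zero raise a warning.
* **LSCV.** Boundary detection at $10^{-3}$ relative distance from the
  lower bracket edge, plus an explicit comparison with the edge score.
* **Isopleth polygons.** Cell unions are polygonized by cancelling shared
  directed edges and chaining the survivors; counterclockwise rings are
  shells and clockwise rings holes (assigned to the smallest containing
  shell), which GeoJSON consumers reconstruct correctly.

# Known limitations

* Coordinates must be projected planar meters; geographic-looking input is
  refused with guidance rather than reprojected.
* Hull-family isopleth areas are reported at the grid grain (cell count ×
  grain²), consistent with the AUC framework's fixed-grain view; they
  converge to exact polygon-union areas only as the grain shrinks. The
  test suite checks them against an exact inclusion–exclusion oracle on
  small instances.
* The SLCA step rule and the biased-random-bridge inflation constant are
  documented package choices where the source descriptions underdetermine
  the algorithm; both are isolated and oracle-tested so a revision changes
  one place.
* The plug-in pilot is a single scalar on sphered data (one refinement
  stage); heavy multimodality can bias the pilot, though the AMISE
  minimization that follows is exact given the estimated functionals.
* AUC compares cell rankings only. Estimators differing by a monotone
  rescaling of their surface are indistinguishable by design; this is a
  feature for estimator selection, not a defect, but it means AUC must not
  be read as a calibration measure.
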