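Package: rangeselect
Title: Home-Range Estimator Selection by Area-Under-the-Curve
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A suite of eight home-range estimators for animal telemetry data
    (minimum convex polygon and local convex hulls, single-linkage cluster and
    characteristic hull polygons, kernel density estimators with reference,
    plug-in and least-squares cross-validation bandwidths, Brownian bridge and
    dynamic Brownian bridge movement models, and a movement-based kernel
    density estimator built on biased random bridges), together with an
    area-under-the-curve (AUC) goodness-of-fit framework that scores how well
    each estimator's utilization-distribution isopleths fit the relocations,
    and the downstream statistical comparison (Kruskal-Wallis tests, Bonferroni
    pairwise comparisons, random-intercept mixed models on logit-AUC, and AICc
    model selection). A seedable simulator of home-ranging movement and of
    GPS/VHF observation processes (duty cycles, fix success, location error)
    lets the full comparison run without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    lme4,
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
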