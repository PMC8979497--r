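Package: ulperf
Title: Sensor-Based Categorization of Upper-Limb Performance in Daily Life
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes twelve accelerometer-derived upper-limb (UL) performance
    variables from bilateral wrist-worn recordings (activity-count durations,
    magnitudes, variability, use and magnitude ratios, jerk asymmetry, and
    spectral arc length smoothness), runs the variable-reduction by
    cluster-count k-means model ladder (Hopkins clustering tendency, principal
    component analysis, elbow/silhouette/gap diagnostics, MANOVA-refit AIC),
    and freezes the final five-variable, five-cluster solution into a named
    category model that classifies new subjects into five ordered upper-limb
    performance categories. A synthetic-data generator emulates 24-hour
    bilateral recordings with the statistical structure the analysis assumes,
    so every stage is testable without access to clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    grDevices,
    graphics,
    utils,
    signal,
    cluster,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
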