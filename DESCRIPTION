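Package: groupdelim
Title: Spatial Delimitation of Animal Groups and Data-Driven Proximity Thresholds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for delimiting groups of animals observed in instantaneous
    field snapshots, aimed at delphinid surveys but applicable to any planar
    point observations. Implements the operational spatial-proximity rules in
    common use (chain rule, focal-individual rule, fixed-point rule, and a
    behavior-adaptive chain rule), the singleton/group/sighting unit taxonomy,
    and a standardized procedure for deriving biologically grounded threshold
    distances from the distribution of nearest-neighbor-in-a-constant-direction
    distances: kernel density estimation, antimode (cutoff) detection from the
    density gradient, behavior-stratified and multi-level thresholds, and
    bootstrap stability diagnostics. Includes a hierarchical scene simulator
    (Thomas-process-style Gaussian clusters with behavior-dependent spread,
    optional supergroup nesting, and observer detection truncation) and
    evaluation utilities (adjusted Rand partition agreement, threshold-recovery
    experiments, rule comparisons).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    withr
Config/testthat/edition: 3
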