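Package: introscan
Title: Introgression and Selection Scans for Landrace Populations Typed
    with Codominant and Dominant Markers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify recent introgression from modern crop
    varieties into traditional landraces using mixed marker systems
    (codominant microsatellite-style loci and dominant AFLP-style
    band-presence loci).  Provides Bayesian allele-frequency estimation
    for dominant markers with an inbreeding correction, diversity and
    divergence statistics (effective allele number, unbiased expected
    heterozygosity, Weir-Cockerham F-statistics), a Gibbs sampler for
    model-based admixture clustering of mixed marker data with the
    Evanno delta-K rule, two F_ST-outlier selection scans (an
    island-model simulated-null scan with iterative calibration and a
    reversible-jump MCMC locus-effect model reporting Bayes factors),
    neutral-locus set construction with the neutral-versus-all-loci
    introgression contrast, and a forward Wright-Fisher simulator that
    generates study-scale datasets with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
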