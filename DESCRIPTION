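Package: tautopo
Title: Topological and Geometric Classification of Tau Filament Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Open-curve knot theory applied to amyloid filament backbones.
    Computes the exact Gauss linking integral and writhe of polygonal
    alpha-carbon traces, projection-sampled second Vassiliev measures and
    knotoid detection for open chains, repeat-level linking sign tuples,
    residue-resolved linking matrices ("fingerprints"), side-chain push-off
    ribbon twist, stacked-filament linking, and K-means clustering of the
    resulting global topological features. Includes a synthetic generator of
    helices, knots, knotoids and cross-beta fibril stacks so the whole
    pipeline is testable without structure downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    cluster,
    ggplot2,
    jsonlite,
    stats,
    tibble,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
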