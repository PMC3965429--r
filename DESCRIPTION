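Package: dggefp
Title: Functional PCA and Distance-Based Statistics for DGGE Community Fingerprints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for denaturing gradient gel electrophoresis
    (DGGE) fingerprint analysis of microbial communities: lane intensity
    profiles are background-subtracted, aligned through monotone warps,
    cropped and integrated into 101-bin relative-intensity fingerprints;
    fingerprints are smoothed and decomposed by functional principal
    component analysis (FPCA); Euclidean distances on FPCA scores feed Ward
    clustering, correspondence analysis, vector fitting of individual bins,
    and sequential (Type-I) PERMANOVA on unbalanced factorial designs with
    confounded in-situ levels. Band-derived taxon tags are propagated across
    lanes by gel height and summed into phylum- and class-level abundance
    tables. A synthetic gel generator with planted treatment effects, lane
    warping and a dominant settled-plankton band makes every stage testable
    without real gels.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    ape,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
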