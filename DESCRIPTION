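Package: steppescan
Title: Detecting and Dating Directional Gene Flow from IBD Sharing and
    Admixture Linkage Disequilibrium
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for detecting and dating directional gene flow from a
    source region into a set of focal populations using identity-by-descent
    (IBD) segment sharing and allele-frequency statistics. Implements
    length-binned IBD sharing matrices, the exponential distance-decay
    correlation of sharing with geography, a subtraction-accumulation scan
    for reference populations with correlated excess sharing across focal
    populations (with a random-neighbor randomization null), pooled-neighbor
    permutation tests for excess sharing, the three-population f3 admixture
    test with weighted block-jackknife standard errors, and admixture dating
    from weighted-LD decay curves and ancestry-tract lengths, together with
    a forward simulator of admixed haplotypes and an IBD-sharing network
    generator that provide ground-truthed synthetic inputs for every
    analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    vcfR,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
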