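Package: plastisel
Title: Gene-Expression Plasticity, Thermal Tolerance, and Selection in Urban
    Heat Islands
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A multi-stage inference pipeline linking heat-induced
    gene-expression plasticity to thermal-tolerance adaptation across
    urban-forest population pairs. Identifies candidate thermal-tolerance
    genes by signed gene significance in a weighted co-expression network
    with within-module false-discovery-rate control; classifies each
    candidate's heat-induced plasticity as adaptive or maladaptive per
    lineage from common-garden reaction norms; tests the ancestral-plasticity
    versus evolved-divergence correlation against a matrix-randomization null
    that absorbs regression-toward-the-mean artifact; and contrasts
    population-genomic divergence (Weir-Cockerham FST with kernel smoothing,
    distance-binned linkage disequilibrium, Hardy-Weinberg deviation scans,
    and functional-class enrichment) between plasticity classes and the
    transcriptome-wide background. A seeded synthetic-data generator with
    planted ground truth makes every stage testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
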