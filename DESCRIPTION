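Package: spatialRisk
Title: Cross-Disorder GWAS Risk Mapping in 3D Chromatin Domain Models
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Maps two genome-wide association study (GWAS) risk
    architectures onto a chrom3D-style diploid bead model of the nucleus,
    identifies chromatin domains shared between the two traits, detects
    "Euclidean hot spots" of spatially clustered shared-risk domains with
    shuffling-based empirical significance, calls significant Hi-C contacts
    with a distance-stratified binomial model, extracts the cross-disorder
    risk interactome at bin resolution, and tests enrichment of cis-eQTLs
    in risk-interconnecting contacts by permutation. Ships a synthetic-data
    generator that emulates every input (domain segmentations, bead
    coordinates, sparse contact matrices with power-law distance decay,
    risk-variant sets, eQTL catalogs) with planted, recorded ground truth,
    so the full pipeline is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    mclust,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
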