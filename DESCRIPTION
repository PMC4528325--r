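Package: conmapLD
Title: Consensus Genetic Maps and Kinship-Adjusted Linkage Disequilibrium
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Construction of weighted consensus linkage maps from multiple
    mapping populations and analysis of linkage disequilibrium adjusted for
    kinship or subpopulation structure.  Implements genotype information
    content (GIC) marker selection and map weighting, locus quality control
    for full-sib and haploid mapping populations (segregation distortion,
    Mendelian-error inference, two-point suspect-linkage diagnostics, anchor
    selection), a deterministic weighted map merger with minimum-weight
    conflict resolution and monotone least-squares consensus positions,
    kernel-density marker-density profiling with a Poisson deviation test,
    and raw plus kinship- or structure-adjusted r-squared LD tabulation with
    decay regression and extended-LD critical values.  A gene-dropping
    simulator generates multi-cohort full-sib, circular multi-family, and
    admixed unrelated populations with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
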