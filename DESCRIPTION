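Package: scnacompare
Title: Cohort-Comparative Analysis of Somatic Copy-Number Alterations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing somatic copy-number alteration (SCNA)
    landscapes between tumor cohorts from segmented SNP-array profiles.
    Implements in-silico admixture removal (ISAR) given tumor purity and
    ploidy, genomic-disruption scoring, arm-level and focal event calling,
    EIGENSTRAT-style genotype PCA for ancestry assignment, support-vector
    classification of chromosomal instability (CIN) from arm-level copy
    features, a simplified G-score scan for recurrent focal regions with a
    cyclic-shift permutation null, and a stratified permutation test with
    Benjamini-Hochberg FDR and an underpowered-locus filter for detecting
    cohort-differential focal events. A synthetic-cohort generator with
    planted ground truth supports calibration and validation end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
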