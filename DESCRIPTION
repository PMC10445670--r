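Package: ystrkit
Title: Y-STR Haplotype Statistics, Mutation-Rate Estimation and
    Repeat-Structure Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for forensic Y chromosomal short tandem repeat (Y-STR)
    analysis: allele and haplotype frequency estimation, forensic
    parameters (gene/haplotype diversity, discrimination capacity,
    fraction of unique haplotypes) over configurable marker panels,
    detection and classification of father-son mutations under the
    stepwise mutation model with exact binomial (Clopper-Pearson)
    confidence intervals, parsing of bracketed repeat-structure
    nomenclature with sequence-variant classification, mutation-pattern
    analyses (allele size, motif complexity, repeat-unit length,
    paternal age), and a synthetic pedigree generator with known
    ground truth. Includes a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    optparse
Suggests:
    readxl,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
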