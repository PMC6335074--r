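Package: zwscan
Title: Sex-Determining Region Discovery from Pooled Sequencing in ZW Plants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for locating heterogametic-sex-specific genomic regions
    from bulked-segregant (pool-seq) coverage and allele-ratio data, as used
    to map the female-specific (W-linked) region of dioecious trees such as
    red bayberry. Includes a depth-track scanner that finds runs of bases
    covered in one sex pool and absent in the other, copy-number-aware
    binomial tests for sex-linked SNPs with ghost (paralog-derived) variant
    flagging, linkage-map-driven scaffold anchoring into pseudochromosomes
    (chimera splitting, marker-pair majority orientation, AGP output),
    haploblock aggregation with recombination-frequency matrices and
    centromere detection, in-silico PCR scoring of dominant and co-dominant
    sex markers, fourfold-degenerate transversion (4DTv) divergence
    statistics with an HKY-style correction, and a seeded synthetic ZW
    genome simulator so the whole pipeline is testable without external
    data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
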