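Package: rhdtyper
Title: Molecular RHD Genotyping Pipeline for RhD-Negative Pregnancy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates and interprets the molecular work-up of serologically
    RhD-negative pregnant women on a synthetic RHD/RHCE mini-locus: an
    in-silico eight-well PCR-SSP genotyping assay, Sanger-style exon variant
    calling against the RHD*01 reference with ISBT allele assignment, hybrid
    Rhesus-box zygosity typing, a two-tier diagnostic decision tree with
    transfusion/RhIG management guidance, intron-retention analysis of
    splice-acceptor mutations (c.336-1G>A) from mRNA read sets, and
    cell-free fetal DNA based fetal RhD prediction with a two-draw
    resampling policy. All inputs are generated by seeded synthetic-data
    functions, so every stage of the pipeline runs without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
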