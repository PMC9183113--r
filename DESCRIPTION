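Package: satscout
Title: Characterization of Satellite DNA Tandem Repeats and Their rDNA
    Spacer Linkage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Discovery and characterization of satellite DNA tandem
    repeats in genome assemblies and long reads: de novo tandem-period
    detection, monomer segmentation and consensus building, higher-order
    repeat (HOR) subunit decomposition with indel inference between
    repeat families, annotation of 45S rDNA units and their intergenic
    spacers (IGS), classification of repeat copies as independent versus
    IGS-linked with N/P spacer-configuration calls, chromosome-scale HSP
    profiling with genome-fraction estimates at two stringencies, and
    in-silico PCR ladder prediction.  A synthetic-genome simulator with
    machine-readable truth manifests makes every stage testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    rtracklayer,
    stats,
    utils,
    withr,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
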