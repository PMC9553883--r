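Package: FGFR2fusion
Title: Isoform-Aware Annotation of FGFR2 Fusions and In-Silico Diagnostic
    Assay Evaluation
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Annotates DNA rearrangement breakpoints and RNA fusion
    junctions involving FGFR2, the 5' driver of oncogenic gene fusions in
    intrahepatic cholangiocarcinoma. For every isoform of driver and
    partner gene it localizes the breakpoint, decides reading-frame
    status, kinase-domain retention and the oncogenic mechanism
    (C-terminal truncation versus partner-driven enhanced dimerisation),
    and surfaces isoform-dependent conflicts. Declarative models of six
    diagnostic assay classes (break-apart and dual-fusion FISH, 5'/3'
    imbalance, amplicon, single-primer-extension and hybrid-capture NGS)
    predict per event whether each assay would detect it and what it
    could report. A synthetic cohort generator reproduces the published
    fusion architecture (intron-17-dominant breakpoints, bridged and
    partnerless rearrangements, close-proximity partners), and renderers
    emit standardized clinical RNA/DNA fusion reports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: GeneFusionDetection, StructuralVariation, Software, Sequencing
RoxygenNote: 7.3.3
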