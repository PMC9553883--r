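## Shared fixtures, built once per test run.

fixFgfr2 <- fgfr2GeneModel()
fixModel <- fusionGeneModel()
fixDesigns <- bundledAssayDesigns(fixModel)

fixIso <- function(tx) getIsoform(fixModel, tx)

testMeta <- list(assay_description = "targeted RNA/DNA NGS (hybrid capture)",
                 tumour_cell_content = "60%",
                 nucleic_acid_quality = "adequate",
                 library_quality = "adequate",
                 build = "hg19")

## A 1-based position inside FGFR2 intron 17 (between exons 17 and 18 in
## transcript order; the gene is on the minus strand).
intron17Pos <- function(model = fixModel, offset = 2500L) {
    ex <- exons(getIsoform(model, "NM_000141.4"))
    lab <- S4Vectors::mcols(ex)$exon_label
    IRanges::end(ex[lab == "18"]) + offset
}

## Minimal single-exon plus-strand toy isoform: 303 nt exon = CDS.
toyIsoform <- function(strand = "+") {
    aa <- c("M", rep(c("A", "G", "L"), length.out = 99L))
    prot <- paste0(aa, collapse = "")
    cds <- paste0(vapply(strsplit(paste0(prot, "*"), "")[[1]], function(a)
        switch(a, M = "ATG", A = "GCT", G = "GGT", L = "CTG", `*` = "TAA"),
        ""), collapse = "")
    transcriptIsoform("toy1", "TOY", "chrT", strand,
                      exonStarts = 1001L, exonWidths = 303L,
                      cdsStart = 1L, cdsEnd = 303L, sequence = cds)
}
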