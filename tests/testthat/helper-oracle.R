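## Independent reading-frame oracle: concatenate the retained 5' CDS
## fragment with the partner transcript suffix, translate with Biostrings,
## and declare the junction in-frame iff translation terminates exactly at
## the partner's own stop codon. Shares no code with frameStatus(), which
## decides by codon-phase arithmetic.

oracleInFrame <- function(model, tx5, exon5, offset5, tx3, exon3, offset3) {
    iso5 <- getIsoform(model, tx5)
    iso3 <- getIsoform(model, tx3)
    w5 <- IRanges::width(exons(iso5))
    lab5 <- S4Vectors::mcols(exons(iso5))$exon_label
    r5 <- match(as.character(exon5), lab5)
    prefix <- sum(w5[seq_len(r5)]) - offset5
    cds5 <- cdsBounds(iso5)
    l5 <- min(prefix, cds5[["end"]]) - cds5[["start"]] + 1L
    stopifnot(l5 > 0L)

    w3 <- IRanges::width(exons(iso3))
    lab3 <- S4Vectors::mcols(exons(iso3))$exon_label
    r3 <- match(as.character(exon3), lab3)
    p3 <- (if (r3 > 1L) sum(w3[seq_len(r3 - 1L)]) else 0L) + 1L + offset3
    cds3 <- cdsBounds(iso3)
    if (p3 < cds3[["start"]] || p3 > cds3[["end"]] - 3L)
        return(NA)   # outside the partner CDS: no oracle verdict

    frag5 <- Biostrings::subseq(txSequence(iso5), cds5[["start"]],
                                cds5[["start"]] + l5 - 1L)
    frag3 <- Biostrings::subseq(txSequence(iso3), p3,
                                length(txSequence(iso3)))
    concat <- Biostrings::xscat(frag5, frag3)
    nCodon <- length(concat) %/% 3L
    aa <- suppressWarnings(Biostrings::translate(
        Biostrings::subseq(concat, 1L, nCodon * 3L)))
    stops <- IRanges::start(Biostrings::matchPattern("*", aa))
    if (length(stops) == 0L) return(FALSE)
    # nt position (in concat) where the partner's own stop codon begins
    partnerStopAt <- l5 + (cds3[["end"]] - 2L) - p3 + 1L
    identical((min(stops) - 1L) * 3L + 1L, as.integer(partnerStopAt))
}

## random junction draw across the toy partners (junctions constrained to
## the partner CDS so the oracle has a verdict)
randomJunction <- function(model) {
    partnerTx <- sample(c("NM_001080512.3", "NM_005436.5", "NM_007041.3",
                          "NM_006997.4", "NM_001352.4", "NM_002285.3",
                          "NM_016628.5"), 1L)
    iso3 <- getIsoform(model, partnerTx)
    n3 <- length(exons(iso3))
    exon3 <- sample(2:n3, 1L)
    offset3 <- sample(0:25, 1L)
    exon5 <- as.character(sample(5:17, 1L))
    offset5 <- sample(0:25, 1L)
    list(tx5 = "NM_000141.4", exon5 = exon5, offset5 = offset5,
         gene3 = geneSymbol(iso3), tx3 = partnerTx,
         exon3 = as.character(exon3), offset3 = offset3)
}
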