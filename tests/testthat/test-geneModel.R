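test_that("the packaged FGFR2 model reproduces the published isoform facts", {
    iso <- fixIso("NM_000141.4")
    expect_length(exons(iso), 18L)
    expect_identical(proteinLength(iso), 821L)
    expect_identical(proteinLength(fixIso("NM_022970.3")), 822L)

    # IIIb differs from IIIc only by the alternative eighth exon
    exC <- exons(iso); exB <- exons(fixIso("NM_022970.3"))
    same <- IRanges::start(exC) == IRanges::start(exB) &
            IRanges::width(exC) == IRanges::width(exB)
    expect_identical(which(!same), 8L)

    # the C3 variant lacks the first exon, ends in an alternative last exon
    # and its protein is the IIIb protein without the last 53 aa
    isoC3 <- fixIso("NM_001144913")
    expect_identical(proteinLength(isoC3), 822L - 53L)
    labs <- S4Vectors::mcols(exons(isoC3))$exon_label
    expect_false("1" %in% labs)
    expect_identical(labs[length(labs)], "C3")
    expect_identical(as.character(isoformProtein(isoC3)),
                     substr(as.character(isoformProtein(fixIso("NM_022970.3"))),
                            1L, 769L))

    # gene locus: minus strand of chr10 at the hg19 coordinates
    locus <- geneLoci(fixFgfr2)["FGFR2"]
    expect_identical(as.character(GenomicRanges::strand(locus)), "-")
    expect_identical(IRanges::start(locus), 123237844L)
    expect_identical(IRanges::end(locus), 123357972L)

    # kinase domain at aa 481-757 on the canonical isoform
    dom <- proteinDomains(fixFgfr2, "NM_000141.4")
    kin <- dom[dom$name == "kinase", ]
    expect_identical(c(kin$aa_start, kin$aa_end), c(481L, 757L))

    # 26 described exonic regions across the extended catalog
    expect_length(exonicRegions(fixFgfr2, "FGFR2"), 26L)
})

test_that("the YLDL motif sits at aa 769-772 of the canonical protein and nowhere later", {
    hits <- locateMotif(fixIso("NM_000141.4"), "YLDL")
    expect_identical(hits[length(hits)], 769L)
    expect_identical(locateMotif(fixIso("NM_022970.3"), "YLDL"), 770L)
    expect_length(locateMotif(fixIso("NM_001144913"), "YLDL"), 0L)
})

test_that("locateMotif handles degenerate motifs", {
    iso <- toyIsoform()
    expect_length(locateMotif(iso, "WWWW"), 0L)
    prot <- as.character(isoformProtein(iso))
    expect_identical(locateMotif(iso, prot), 1L)
    expect_error(locateMotif(iso, ""), "non-empty")
})

test_that("protein length is CDS/3 minus the stop codon", {
    expect_identical(proteinLength(toyIsoform()), 100L)
    nc <- transcriptIsoform("nc1", "TOY", "chrT", "+", 1L, 100L)
    expect_error(proteinLength(nc), "non-coding")
})

test_that("genomic-to-transcript mapping respects strand and flags flanks", {
    # minus-strand toy exon on [1001, 1100]: the highest genomic base is cDNA 1
    iso <- transcriptIsoform("mt1", "TOY", "chrT", "-", 1001L, 100L)
    expect_identical(genomicToTranscript(iso, 1100L)$cdna, 1L)
    expect_identical(genomicToTranscript(iso, 1001L)$cdna, 100L)
    expect_identical(genomicToTranscript(iso, 1150L)$region, "upstream")
    expect_identical(genomicToTranscript(iso, 950L)$region, "downstream")
    expect_error(genomicToTranscript(iso, 1050L, chrom = "chrZ"), "chromosome")

    # a position between fixture exons 17 and 18 is intron 17
    m <- genomicToTranscript(fixIso("NM_000141.4"), intron17Pos())
    expect_identical(m$region, "intron")
    expect_identical(m$index, 17L)
})

test_that("transcript/genomic mapping round-trips over every exonic base", {
    for (iso in isoforms(fixFgfr2)) {
        pos <- unlist(lapply(seq_along(exons(iso)), function(k)
            IRanges::start(exons(iso))[k]:IRanges::end(exons(iso))[k]))
        mp <- genomicToTranscript(iso, pos)
        expect_true(all(mp$region == "exon"))
        expect_identical(sort(mp$cdna), seq_len(sum(IRanges::width(exons(iso)))))
        expect_identical(transcriptToGenomic(iso, mp$cdna), pos)
    }
})

test_that("mirroring an isoform to the other strand preserves cDNA-level facts", {
    iso <- fixIso("NM_000141.4")
    C <- 250000000L
    ex <- exons(iso)
    mirrored <- transcriptIsoform("mirror", "FGFR2", "chr10", "+",
        exonStarts = C - IRanges::end(ex),
        exonWidths = IRanges::width(ex),
        labels = S4Vectors::mcols(ex)$exon_label,
        cdsStart = cdsBounds(iso)[["start"]], cdsEnd = cdsBounds(iso)[["end"]],
        sequence = as.character(txSequence(iso)))
    expect_identical(proteinLength(mirrored), proteinLength(iso))
    expect_identical(locateMotif(mirrored, "YLDL"), locateMotif(iso, "YLDL"))
    # cDNA coordinates agree for mirrored genomic positions
    p <- c(IRanges::start(ex)[3], IRanges::end(ex)[17])
    expect_identical(genomicToTranscript(mirrored, C - p)$cdna,
                     genomicToTranscript(iso, p)$cdna)
})

test_that("gene models load from fixture JSON and from GFF3", {
    tf <- tempfile(fileext = ".json")
    geneModelToJson(fixFgfr2, tf)
    m2 <- loadGeneModel(tf)
    expect_setequal(names(isoforms(m2)), names(isoforms(fixFgfr2)))
    expect_identical(proteinLength(getIsoform(m2, "NM_000141.4")), 821L)
    expect_identical(locateMotif(getIsoform(m2, "NM_000141.4"), "YLDL"), 769L)
    expect_length(exonicRegions(m2, "FGFR2"), 26L)

    gff <- c("##gff-version 3",
        "chr1\ttoy\tgene\t1001\t1400\t.\t+\t.\tID=g1;Name=TOY",
        "chr1\ttoy\tmRNA\t1001\t1400\t.\t+\t.\tID=t1;Parent=g1",
        "chr1\ttoy\texon\t1001\t1303\t.\t+\t.\tID=e1;Parent=t1",
        "chr1\ttoy\tCDS\t1001\t1303\t.\t+\t.\tID=c1;Parent=t1")
    tg <- tempfile(fileext = ".gff3")
    writeLines(gff, tg)
    mg <- loadGeneModel(tg)
    expect_length(exons(getIsoform(mg, "t1")), 1L)
    expect_identical(proteinLength(getIsoform(mg, "t1")), 100L)

    # an mRNA without exon children is rejected
    writeLines(gff[-4], tg)
    expect_error(loadGeneModel(tg), "no exon")

    # CDS length not divisible by 3 is rejected
    bad <- gff
    bad[5] <- "chr1\ttoy\tCDS\t1001\t1302\t.\t+\t.\tID=c1;Parent=t1"
    writeLines(bad, tg)
    expect_error(loadGeneModel(tg), "divisible by 3")
})

test_that("isoform validity catches inconsistent structures", {
    expect_error(transcriptIsoform("bad", "X", "chr1", "+",
        exonStarts = c(100L, 150L), exonWidths = c(100L, 50L)),
        "overlap")
    expect_error(transcriptIsoform("bad", "X", "chr1", "-",
        exonStarts = c(100L, 500L), exonWidths = c(50L, 50L)),
        "transcript order")
    expect_error(transcriptIsoform("bad", "X", "chr1", "+",
        exonStarts = 100L, exonWidths = 100L, cdsStart = 1L, cdsEnd = 100L),
        "divisible by 3")
})
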