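iso141 <- fixIso("NM_000141.4")
dom141 <- proteinDomains(fixModel, "NM_000141.4")

test_that("breakend localization assigns introns, flanks and CDS/UTR exons", {
    loc <- localizeBreakend(breakend("chr10", intron17Pos(), "right"), iso141)
    expect_identical(loc$region, "intron")
    expect_identical(loc$index, 17L)

    # transcript-upstream of a minus-strand gene = genomically above exon 1
    up <- localizeBreakend(breakend("chr10", 123357950L, "right"), iso141)
    expect_identical(up$region, "upstream")

    ex <- exons(iso141)
    lab <- S4Vectors::mcols(ex)$exon_label
    inE18cds <- IRanges::end(ex[lab == "18"]) - 10L   # CDS-proximal end
    loc18 <- localizeBreakend(breakend("chr10", inE18cds, "right"), iso141)
    expect_identical(loc18$region, "exon (CDS)")
    expect_identical(loc18$label, "18")

    utr18 <- IRanges::start(ex[lab == "18"]) + 10L    # 3' UTR end
    expect_identical(localizeBreakend(breakend("chr10", utr18, "right"),
                                      iso141)$region, "exon (UTR)")
    expect_error(localizeBreakend(breakend("chr7", 1000L, "right"), iso141),
                 "chromosome")
})

test_that("kinase retention follows the exon-17/intron-17/exon-18 rule", {
    locAt <- function(pos) localizeBreakend(breakend("chr10", pos, "right"),
                                            iso141)
    ex <- exons(iso141)
    lab <- S4Vectors::mcols(ex)$exon_label

    k17 <- kinaseRetained(locAt(intron17Pos()), iso141, dom141)
    expect_true(k17$retained); expect_false(k17$warning)

    # intron 16 (between exons 16 and 17): kinase lost
    i16 <- IRanges::end(ex[lab == "17"]) + 500L
    k16 <- kinaseRetained(locAt(i16), iso141, dom141)
    expect_false(k16$retained); expect_false(k16$warning)

    # exon 18 CDS: retained
    e18 <- IRanges::end(ex[lab == "18"]) - 5L
    expect_true(kinaseRetained(locAt(e18), iso141, dom141)$retained)

    # inside exon 17 upstream of the kinase C-terminal codon: the positional
    # rule says involved, the amino-acid rule says truncated -> flagged
    early17 <- transcriptToGenomic(iso141,
        cdsBounds(iso141)[["start"]] - 1L + 3L * 740L)
    kEarly <- kinaseRetained(locAt(early17), iso141, dom141)
    expect_false(kEarly$retained)
    expect_true(kEarly$warning)
})

test_that("kinase retention is monotone as the 5' breakend moves 3'-ward", {
    ex <- exons(iso141)
    # walk genomically downward (= transcript-3'-ward on the minus strand)
    pos <- sort(unique(c(
        seq(IRanges::start(ex)[1], IRanges::end(ex)[18] - 100L,
            by = -4999L),
        IRanges::start(ex) + 3L)), decreasing = TRUE)
    ret <- vapply(pos, function(p) kinaseRetained(
        localizeBreakend(breakend("chr10", p, "right"), iso141),
        iso141, dom141)$retained, TRUE)
    expect_true(all(diff(as.integer(ret)) >= 0))  # FALSE..FALSE TRUE..TRUE
})

test_that("frame status distinguishes partner isoforms with different start codons", {
    # junction after FGFR2 exon 17 into KCTD1 'exon 2' (shared across its
    # isoforms): upstream of the canonical start codon -> no partner CDS,
    # in-frame on the alternative isoforms
    j <- fusionJunction("jk", "FGFR2", "NM_000141.4", "17", 0L,
                        "KCTD1", "NM_001142730.3", "2", 0L,
                        evidence = readEvidence(10, 5, 10))
    fs <- frameStatus(j, fixModel)
    expect_identical(fs$frame[fs$isoform3 == "NM_001142730.3"], "no_cds_3p")
    expect_identical(fs$frame[fs$isoform3 == "NM_001258222.3"], "in_frame")
    expect_identical(fs$frame[fs$isoform3 == "NM_198991.3"], "in_frame")

    # unknown partner gene: indeterminate, not an error
    ju <- fusionJunction("ju", "FGFR2", "NM_000141.4", "17", 0L,
                         "NOVELGENE", "NM_000000.0", "2", 0L, novel3 = TRUE)
    expect_identical(frameStatus(ju, fixModel)$frame, "indeterminate")
})

test_that("frame status agrees with the translation oracle on random junctions", {
    set.seed(20240917)
    n <- 0L
    while (n < 1000L) {
        rj <- randomJunction(fixModel)
        oracle <- oracleInFrame(fixModel, rj$tx5, rj$exon5, rj$offset5,
                                rj$tx3, rj$exon3, rj$offset3)
        if (is.na(oracle)) next
        j <- fusionJunction(paste0("r", n), "FGFR2", rj$tx5, rj$exon5,
                            rj$offset5, rj$gene3, rj$tx3, rj$exon3, rj$offset3)
        fs <- frameStatus(j, fixModel)
        verdict <- fs$frame[fs$isoform3 == rj$tx3]
        expect_identical(verdict == "in_frame", oracle,
            info = sprintf("junction %s+%d :: %s %s+%d", rj$exon5, rj$offset5,
                           rj$tx3, rj$exon3, rj$offset3))
        n <- n + 1L
    }
})

test_that("mechanism classification separates dimerisation gain from truncation", {
    # in-frame junction gaining a coiled-coil: enhanced dimerisation
    jt <- fusionJunction("jt", "FGFR2", "NM_000141.4", "17", 0L,
                         "TACC2", "NM_006997.4", "2", 0L,
                         evidence = readEvidence(10, 5, 10))
    recT <- annotationRecords(annotateEvent(jt, fixModel))
    canT <- recT[recT$isoform5 == "NM_000141.4", ][1, ]
    expect_identical(canT$mechanism, "enhanced_dimerisation")
    expect_true(canT$competent)
    expect_identical(canT$retained_partner_domains, "coiled-coil")

    # in-frame junction into a partner without a dimerisation domain: the
    # YLDL loss itself is the mechanism, and frame is irrelevant to it
    ja <- fusionJunction("ja", "FGFR2", "NM_000141.4", "17", 0L,
                         "ATE1", "NM_007041.3", "12", 0L,
                         evidence = readEvidence(10, 5, 10))
    recA <- annotationRecords(annotateEvent(ja, fixModel))
    canA <- recA[recA$isoform5 == "NM_000141.4", ][1, ]
    expect_identical(canA$mechanism, "c_terminal_truncation")
    expect_identical(canA$lost_motifs, "YLDL")
    expect_true(canA$competent)
    expect_false(hasIsoformConflict(annotateEvent(ja, fixModel)))

    # partnerless rearrangement after exon 17: truncation forced
    evP <- breakpointEvent("p1", breakend("chr10", intron17Pos(), "right"),
                           evidence = readEvidence(10, 5, 10))
    recP <- annotationRecords(annotateEvent(evP, fixModel))
    expect_true(all(recP$mechanism == "c_terminal_truncation"))
    expect_true(all(grepl("YLDL", recP$lost_motifs[
        recP$isoform5 != "NM_001144913"])))

    # breakend in intron 16: no kinase, no mechanism, not competent
    ex <- exons(iso141)
    i16 <- IRanges::end(ex[S4Vectors::mcols(ex)$exon_label == "17"]) + 500L
    ev16 <- breakpointEvent("p2", breakend("chr10", i16, "right"),
        breakend("chr10", 60202000L, "left"),
        evidence = readEvidence(10, 5, 10))
    rec16 <- annotationRecords(annotateEvent(ev16, fixModel))
    can16 <- rec16[rec16$isoform5 == "NM_000141.4", ]
    expect_true(all(can16$mechanism == "none"))
    expect_false(any(rec16$competent))
})

test_that("mechanism and competence invariants hold across a simulated cohort", {
    co <- simulateCohort(cohortParams(nEvents = 120L, seed = 99L), fixModel)
    tab <- annotationTable(annotateCohort(c(co$events, co$junctions),
                                          fixModel))
    # exclusivity: a record is never both mechanisms; competent => kinase
    expect_true(all(tab$mechanism %in% c("enhanced_dimerisation",
        "c_terminal_truncation", "none", "indeterminate")))
    expect_true(all(tab$kinase_retained[tab$competent]))
    expect_true(all(tab$mechanism[tab$competent] != "none"))
    # enhanced dimerisation only with an intact frame
    expect_true(all(tab$frame[tab$mechanism == "enhanced_dimerisation"] ==
                    "in_frame"))
})

test_that("bridged DNA events are indeterminate; the expressed junction resolves them", {
    ev <- breakpointEvent("br", breakend("chr10", intron17Pos(), "right"),
        breakend("chr19", 49102000L, "right"), partnerStatus = "ambiguous",
        insertSeq = strrep("GGCCGGGCGCGGTGGCTCAC", 4L),
        insertOrigin = "repeat:AluSx", evidence = readEvidence(8, 4, 20))
    recD <- annotationRecords(annotateEvent(ev, fixModel))
    expect_true(all(recD$mechanism == "indeterminate"))
    expect_true(all(recD$frame == "indeterminate"))

    j <- fusionJunction("br", "FGFR2", "NM_000141.4", "17", 0L,
                        "DBP", "NM_001352.4", "2", 0L,
                        evidence = readEvidence(30, 12, 25))
    recR <- annotationRecords(annotateEvent(j, fixModel))
    can <- recR[recR$isoform5 == "NM_000141.4", ]
    expect_identical(unique(can$frame), "in_frame")
    expect_identical(unique(can$mechanism), "enhanced_dimerisation")
})

test_that("isoform conflicts are surfaced for DNA breakpoints near alternative starts", {
    ev <- breakpointEvent("kctd1", breakend("chr10", intron17Pos(), "right"),
        breakend("chr18", 24001000L, "left"),
        evidence = readEvidence(12, 6, 20))
    a <- annotateEvent(ev, fixModel)
    expect_true(hasIsoformConflict(a))
    rec <- annotationRecords(a)
    can <- rec[rec$isoform5 == "NM_000141.4", ]
    expect_setequal(unique(can$frame), c("no_cds_3p", "in_frame"))
    expect_setequal(unique(can$mechanism),
                    c("c_terminal_truncation", "enhanced_dimerisation"))
})

test_that("annotation errors on events outside any modeled driver gene", {
    ev <- breakpointEvent("nowhere", breakend("chr7", 1000L, "right"))
    expect_error(annotateEvent(ev, fixModel), "no modeled gene")
    j <- fusionJunction("jx", "NOSUCH", "tx", "1", 0L, "ATE1",
                        "NM_007041.3", "2", 0L)
    expect_error(annotateEvent(j, fixModel), "absent")
})
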