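mkEvent <- function(id, chrom3, pos3, ..., pos5 = intron17Pos()) {
    breakpointEvent(id, breakend("chr10", pos5, "right"),
        if (is.null(chrom3)) NULL else breakend(chrom3, pos3, "left"),
        evidence = readEvidence(12, 6, 24), ...)
}

test_that("break-apart FISH misses close partners and 3' deletions", {
    ba <- fixDesigns$ba_fish
    # ATE1-like partner ~140 kb away, probe resolution 1 Mb
    vClose <- evaluateAssay(ba, mkEvent("c1", "chr10", 123510000L), fixModel)
    expect_false(isDetected(vClose))
    expect_identical(failureMode(vClose), "close_proximity")

    # distant partner on another chromosome
    vFar <- evaluateAssay(ba, mkEvent("c2", "chr19", 49102000L), fixModel)
    expect_true(isDetected(vFar))
    expect_identical(partnerResolution(vFar), "agnostic_unidentified")
    expect_false(vFar@frameDeterminable)

    # intragenic 3' deletion: probes never separate
    ex <- exons(fixIso("NM_000141.4"))
    utr <- IRanges::start(ex[S4Vectors::mcols(ex)$exon_label == "18"]) + 30L
    vDel <- evaluateAssay(ba, mkEvent("c3", "chr10", utr), fixModel)
    expect_false(isDetected(vDel))
    expect_identical(failureMode(vDel), "not_covered")

    # driver breakend outside the probe gap
    vOut <- evaluateAssay(ba, mkEvent("c4", "chr19", 49102000L,
                                      pos5 = 200000000L), fixModel)
    expect_false(isDetected(vOut))
})

test_that("dual-fusion FISH is limited to its designed partner", {
    dual <- fixDesigns$dual_fish
    vHit <- evaluateAssay(dual, mkEvent("d1", "chr10", 60202000L), fixModel)
    expect_true(isDetected(vHit))
    expect_identical(partnerResolution(vHit), "specific")

    vMiss <- evaluateAssay(dual, mkEvent("d2", "chr10", 123510000L), fixModel)
    expect_false(isDetected(vMiss))
    expect_identical(failureMode(vMiss), "wrong_partner")

    vNone <- evaluateAssay(dual, mkEvent("d3", NULL, NULL,
                                         partnerStatus = "unmapped"), fixModel)
    expect_false(isDetected(vNone))
})

test_that("the imbalance assay detects any 3' loss but cannot classify it", {
    imb <- fixDesigns$imbalance
    fusion <- evaluateAssay(imb, NULL, fixModel, expression = c(100, 20))
    del <- evaluateAssay(imb, NULL, fixModel, expression = c(100, 5))
    wt <- evaluateAssay(imb, NULL, fixModel, expression = c(100, 98))
    expect_true(isDetected(fusion))
    expect_true(isDetected(del))
    expect_false(isDetected(wt))
    expect_identical(failureMode(wt), "below_threshold")
    # fusion and deletion verdicts are indistinguishable in shape
    expect_identical(partnerResolution(fusion), partnerResolution(del))
    expect_identical(fusion@frameDeterminable, del@frameDeterminable)
    expect_identical(partnerResolution(fusion), "none")
})

test_that("the amplicon panel reproduces the CCDC6 worked example", {
    # four junctions on CCDC6 exons 1-4; primers exist for exons 1-2 only
    js <- lapply(1:4, function(k) fusionJunction(sprintf("cc%d", k),
        "FGFR2", "NM_000141.4", "17", 0L, "CCDC6", "NM_005436.5",
        as.character(k), 0L, evidence = readEvidence(10, 4, 12)))
    verdicts <- vapply(js, function(j)
        isDetected(evaluateAssay(fixDesigns$amplicon, j, fixModel)), TRUE)
    expect_identical(sum(verdicts), 2L)
    expect_identical(verdicts, c(TRUE, TRUE, FALSE, FALSE))
    v3 <- evaluateAssay(fixDesigns$amplicon, js[[3]], fixModel)
    expect_identical(failureMode(v3), "partner_not_in_design")

    # intergenic / unknown 3' sequence can never be designed for
    ji <- fusionJunction("int1", "FGFR2", "NM_000141.4", "17", 0L,
                         "intergenic", "novel", "1", 0L, novel3 = TRUE)
    vi <- evaluateAssay(fixDesigns$amplicon, ji, fixModel)
    expect_false(isDetected(vi))
    expect_identical(failureMode(vi), "partner_not_in_design")

    frac <- cohortCoverage(js, list(amplicon = fixDesigns$amplicon),
                           fixModel)$fractions
    expect_equal(unname(frac), 0.5)
})

test_that("SPE detects partner-agnostically but only on its design isoform", {
    spe <- fixDesigns$spe
    jKnown <- fusionJunction("s1", "FGFR2", "NM_000141.4", "17", 0L,
                             "ATE1", "NM_007041.3", "12", 0L)
    jNovel <- fusionJunction("s2", "FGFR2", "NM_000141.4", "17", 0L,
                             "intergenic", "novel", "1", 0L, novel3 = TRUE)
    jC3 <- fusionJunction("s3", "FGFR2", "NM_001144913", "C3", 0L,
                          "ATE1", "NM_007041.3", "12", 0L)
    v1 <- evaluateAssay(spe, jKnown, fixModel)
    v2 <- evaluateAssay(spe, jNovel, fixModel)
    v3 <- evaluateAssay(spe, jC3, fixModel)
    expect_true(isDetected(v1))
    expect_identical(partnerResolution(v1), "agnostic_identified")
    expect_true(v1@frameDeterminable && v1@expressionAssessed)
    expect_true(isDetected(v2))   # partner read from sequence
    # junction exon absent from NM_000141.4: not covered
    expect_false(isDetected(v3))
    expect_identical(failureMode(v3), "not_covered")
})

test_that("hybrid capture reports bridged events as unresolved rearrangements", {
    hy <- fixDesigns$hyca_dna
    evB <- mkEvent("h1", "chr19", 49102000L, partnerStatus = "ambiguous",
                   insertSeq = strrep("GGCCGGGCGCGGTGGCTCAC", 4L),
                   insertOrigin = "repeat:AluSx")
    vB <- evaluateAssay(hy, evB, fixModel)
    expect_true(isDetected(vB))
    expect_identical(partnerResolution(vB), "agnostic_unidentified")
    expect_identical(failureMode(vB), "bridged_unresolved")
    expect_false(vB@frameDeterminable)

    # the same event at RNA level identifies the partner
    jB <- fusionJunction("h1", "FGFR2", "NM_000141.4", "17", 0L,
                         "DBP", "NM_001352.4", "2", 0L)
    vR <- evaluateAssay(fixDesigns$hyca_rna, jB, fixModel)
    expect_true(isDetected(vR))
    expect_identical(partnerResolution(vR), "agnostic_identified")
    expect_true(vR@frameDeterminable)

    # driver breakend outside the tiled probes
    vOut <- evaluateAssay(hy, mkEvent("h2", "chr19", 49102000L,
                                      pos5 = 123356000L), fixModel)
    expect_false(isDetected(vOut))
    expect_identical(failureMode(vOut), "not_covered")
})

test_that("assay detection sets nest: amplicon within SPE within HyCa-RNA", {
    co <- simulateCohort(cohortParams(nEvents = 250L, seed = 17L), fixModel)
    for (j in co$junctions) {
        a <- isDetected(evaluateAssay(fixDesigns$amplicon, j, fixModel))
        s <- isDetected(evaluateAssay(fixDesigns$spe, j, fixModel))
        h <- isDetected(evaluateAssay(fixDesigns$hyca_rna, j, fixModel))
        expect_true(!a || s)
        expect_true(!s || h)
    }
})

test_that("HyCa-RNA sensitivity is exactly 1 on expressed, captured cohorts", {
    co <- simulateCohort(cohortParams(nEvents = 200L, seed = 23L), fixModel)
    det <- vapply(co$junctions, function(j)
        isDetected(evaluateAssay(fixDesigns$hyca_rna, j, fixModel)), TRUE)
    expect_identical(mean(det), 1)
})

test_that("verdicts are sound and dual-FISH nests inside BA-FISH", {
    co <- simulateCohort(cohortParams(nEvents = 250L, seed = 31L), fixModel)
    for (ev in co$events) {
        for (d in list(fixDesigns$ba_fish, fixDesigns$dual_fish,
                       fixDesigns$hyca_dna)) {
            v <- evaluateAssay(d, ev, fixModel)
            # failure 'none' implies detection; a miss always carries a cause
            expect_true(!identical(failureMode(v), "none") || isDetected(v))
            expect_true(isDetected(v) || !identical(failureMode(v), "none"))
        }
        vDual <- evaluateAssay(fixDesigns$dual_fish, ev, fixModel)
        if (isDetected(vDual)) {
            vBa <- evaluateAssay(fixDesigns$ba_fish, ev, fixModel)
            expect_true(isDetected(vBa) ||
                        identical(failureMode(vBa), "close_proximity"))
        }
    }
})

test_that("the scenario capability matrix matches the published behaviour", {
    cm <- capabilityMatrix(fixDesigns, fixModel)
    m <- cm$matrix
    expect_false(any(unlist(m["wildtype", ])))
    # close partner: BA-FISH misses; imbalance, SPE and HyCa detect
    expect_false(m["close_partner", "ba_fish"])
    expect_true(m["close_partner", "imbalance"])
    expect_true(m["close_partner", "spe"])
    expect_true(m["close_partner", "hyca_rna"])
    # 3' deletion: both FISH designs miss; imbalance detects
    expect_false(m["deletion_3p", "ba_fish"])
    expect_false(m["deletion_3p", "dual_fish"])
    expect_true(m["deletion_3p", "imbalance"])
    # amplicon fails unknown and intergenic partners
    expect_false(m["unknown_partner", "amplicon"])
    expect_false(m["intergenic", "amplicon"])
    expect_true(m["unknown_partner", "spe"])
})

test_that("assay designs round-trip through YAML config", {
    cfg <- list(
        my_ba = list(type = "ba_fish",
            probe5 = list(chrom = "chr10", start = 123360000, end = 123410000),
            probe3 = list(chrom = "chr10", start = 123180000, end = 123230000),
            resolution_bp = 1e6),
        my_amp = list(type = "amplicon", driver_primers = list("17", "18"),
            partner_primers = list(CCDC6 = list("1", "2"))),
        my_spe = list(type = "spe", driver_primers = list("17", "18"),
            design_isoform = "NM_000141.4"),
        my_hyca = list(type = "hyca", level = "RNA",
            captured_exons = list(FGFR2 = as.list(as.character(1:18)))))
    tf <- tempfile(fileext = ".yaml")
    yaml::write_yaml(cfg, tf)
    ds <- readAssayDesigns(tf)
    expect_length(ds, 4L)
    expect_s4_class(ds$my_ba, "BAFishDesign")
    expect_identical(ds$my_ba@resolutionBp, 1e6)
    expect_identical(ds$my_amp@partnerPrimers$CCDC6, c("1", "2"))
    j <- fusionJunction("y1", "FGFR2", "NM_000141.4", "17", 0L,
                        "CCDC6", "NM_005436.5", "2", 0L)
    expect_true(isDetected(evaluateAssay(ds$my_amp, j, fixModel)))

    # the packaged example config parses into all six design classes
    exCfg <- system.file("extdata", "example_designs.yaml",
                         package = "FGFR2fusion")
    exDs <- readAssayDesigns(exCfg)
    expect_length(exDs, 7L)
    expect_true(isDetected(evaluateAssay(exDs$spe_panel, j, fixModel)))

    bed <- tempfile(fileext = ".bed")
    writeProbesBed(fixDesigns$hyca_dna, bed)
    f <- read.table(bed, sep = "\t")
    expect_identical(ncol(f), 4L)
    expect_true(all(f$V2 < f$V3))
})
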