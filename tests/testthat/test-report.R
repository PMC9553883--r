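test_that("fusion labels follow the compact exon-code nomenclature", {
    expect_identical(fusionLabel("FGFR2", "17", "ATE1", "12"),
                     "FGFR2::ATE1 (F17A12)")
    expect_identical(fusionLabel("FGFR2", "17", "BICC1", "3"),
                     "FGFR2::BICC1 (F17B3)")
    # shared initial: the first differing letter disambiguates
    lbl <- fusionLabel("FGFR2", "17", "FOXO1", "2")
    expect_match(lbl, "^FGFR2::FOXO1 \\(FG17FO2\\)$")
    # partnerless events render as a rearrangement phrase, no partner token
    phr <- fusionLabel("FGFR2", "17", NA, region = "intron 17")
    expect_match(phr, "rearrangement")
    expect_false(grepl("::", phr))
})

test_that("fusion labels parse back to their components", {
    cases <- list(c("FGFR2", "17", "ATE1", "12"), c("FGFR2", "18", "BICC1", "3"),
                  c("FGFR2", "17", "KCTD1", "2"), c("FGFR2", "5", "WAC", "2"))
    for (cs in cases) {
        p <- parseFusionLabel(fusionLabel(cs[1], cs[2], cs[3], cs[4]))
        expect_identical(unlist(p),
                         c(gene5 = cs[1], exon5 = cs[2],
                           gene3 = cs[3], exon3 = cs[4]))
    }
    expect_null(parseFusionLabel(fusionLabel("FGFR2", "17", NA)))
})

test_that("RNA reports carry the five mandated items and validate", {
    j <- fusionJunction("r1", "FGFR2", "NM_000141.4", "17", 0L,
                        "TACC2", "NM_006997.4", "2", 0L,
                        evidence = readEvidence(24, 9, 30))
    rep <- renderRnaReport(j, annotateEvent(j, fixModel), testMeta)
    f <- reportFields(rep)
    expect_equal(f$fusion_read_ratio, 33 / 63)
    expect_identical(f$reads$split, 24L)
    expect_identical(f$genes$tx3, "NM_006997.4")
    expect_identical(f$junction_exons$exon5, "17")
    expect_match(f$frame_statement, "in-frame")
    expect_match(f$domain_statement, "intact")
    v <- validateReport(rep)
    expect_true(v$valid)
    expect_length(v$missing, 0L)
    # machine-readable JSON round-trips
    tf <- tempfile(fileext = ".json")
    reportToJson(rep, tf)
    back <- jsonlite::fromJSON(tf)
    expect_identical(back$genes$gene3, "TACC2")
    expect_identical(back$vicc$five_prime$transcript, "NM_000141.4")
})

test_that("RNA report rendering refuses incomplete or evidence-free input", {
    j0 <- fusionJunction("r2", "FGFR2", "NM_000141.4", "17", 0L,
                         "ATE1", "NM_007041.3", "12", 0L,
                         evidence = readEvidence(0, 0, 0))
    ann <- annotateEvent(j0, fixModel)
    expect_error(renderRnaReport(j0, ann, testMeta), "ratio")
    jNoTx <- fusionJunction("r3", "FGFR2", "", "17", 0L,
                            "ATE1", "NM_007041.3", "12", 0L,
                            evidence = readEvidence(5, 2, 8))
    expect_error(renderRnaReport(jNoTx, annotateEvent(jNoTx, fixModel),
                                 testMeta), "tx5")
    expect_error(renderRnaReport(j0, ann, testMeta[-1]), "assay_description")
})

test_that("out-of-frame truncation fusions report frame and domain correctly", {
    j <- fusionJunction("r4", "FGFR2", "NM_000141.4", "17", 0L,
                        "BICC1", "NM_001080512.3", "3", 1L,
                        evidence = readEvidence(18, 6, 30))
    rep <- renderRnaReport(j, annotateEvent(j, fixModel), testMeta)
    f <- reportFields(rep)
    expect_match(f$frame_statement, "not in-frame")
    expect_match(f$domain_statement, "intact")   # kinase still intact
    expect_match(f$domain_statement, "truncation")
})

test_that("DNA reports state build and use cautious wording when unresolved", {
    ev <- breakpointEvent("d1", breakend("chr10", intron17Pos(), "right"),
        breakend("chr19", 49102000L, "right"), partnerStatus = "ambiguous",
        insertSeq = strrep("GGCCGGGCGCGGTGGCTCAC", 4L),
        insertOrigin = "repeat:AluSx", evidence = readEvidence(9, 5, 40))
    rep <- renderDnaReport(ev, annotateEvent(ev, fixModel), testMeta, fixModel)
    f <- reportFields(rep)
    expect_identical(f$genome_build, "hg19")
    expect_match(f$frame_domain_estimate, "caution")
    expect_match(f$label, "rearrangement")
    expect_match(f$iscn, "^t\\(10;19\\)")
    v <- validateReport(rep)
    expect_true(v$valid)

    # clean intron-17 event with identified partner: both genes, both coords
    ev2 <- breakpointEvent("d2", breakend("chr10", intron17Pos(), "right"),
        breakend("chr10", 60202000L, "left"),
        evidence = readEvidence(14, 8, 30))
    f2 <- reportFields(renderDnaReport(ev2, annotateEvent(ev2, fixModel),
                                       testMeta, fixModel))
    expect_identical(f2$genes$gene3, "BICC1")
    expect_match(f2$breakpoints$three_prime, "^chr10:")
    expect_false(grepl("caution", f2$frame_domain_estimate))

    expect_error(renderDnaReport(ev2, annotateEvent(ev2, fixModel),
                                 testMeta[names(testMeta) != "build"],
                                 fixModel), "build")
})

test_that("every report rendered from a simulated cohort passes the checklist", {
    co <- simulateCohort(cohortParams(nEvents = 40L, seed = 55L), fixModel)
    for (j in co$junctions) {
        rep <- renderRnaReport(j, annotateEvent(j, fixModel), testMeta)
        expect_true(validateReport(rep)$valid, info = j@id)
    }
    for (ev in co$events) {
        if (sum(readCounts(ev@evidence)) == 0L) next
        rep <- renderDnaReport(ev, annotateEvent(ev, fixModel), testMeta,
                               fixModel)
        expect_true(validateReport(rep)$valid, info = ev@id)
    }
    # a hand-stripped report fails, naming the missing field
    f <- reportFields(renderRnaReport(co$junctions[[1]],
        annotateEvent(co$junctions[[1]], fixModel), testMeta))
    f$fusion_read_ratio <- NULL
    bad <- validateReport(f)
    expect_false(bad$valid)
    expect_identical(bad$missing, "fusion_read_ratio")
})
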