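## Synthetic cohort generator. Emulates the published FGFR2 fusion
## architecture: driver breakpoints concentrated in exon 17 / intron 17 /
## exon 18 (intron 17 dominant), heterogeneous partner genes, ~10% bridged
## or intergenic partnerless rearrangements at DNA level, ~4.2% partners in
## close genomic proximity, occasional intragenic 3' deletions and
## out-of-frame junctions. Every event carries ground-truth labels so
## annotation and assay verdicts can be scored.

#' Construct cohort simulation parameters
#'
#' @param nEvents number of events.
#' @param seed RNG seed (all randomness flows through it).
#' @param pBridged fraction of bridged/intergenic partnerless events
#'   (published: ~10\% of cases).
#' @param pClosePartner fraction with a close-proximity partner
#'   (published: 4.2\% of the reference cohort).
#' @param pOutOfFrame,p3pDeletion,pUpstream remaining class fractions.
#' @param breakendWeights distribution of driver breakpoints over
#'   exon 17 / intron 17 / exon 18.
#' @param depth mean read depth for simulated evidence.
#' @return a validated \code{CohortParams}.
#' @export
cohortParams <- function(nEvents = 1000L, seed = 1L,
                         pBridged = 0.10, pClosePartner = 0.042,
                         pOutOfFrame = 0.05, p3pDeletion = 0.03,
                         pUpstream = 0.05,
                         breakendWeights = c(exon17 = 0.15, intron17 = 0.70,
                                             exon18 = 0.15),
                         depth = 200) {
    p <- new("CohortParams", nEvents = as.integer(nEvents),
             seed = as.integer(seed), pBridged = pBridged,
             pClosePartner = pClosePartner, pOutOfFrame = pOutOfFrame,
             p3pDeletion = p3pDeletion, pUpstream = pUpstream,
             breakendWeights = breakendWeights, depth = depth)
    validObject(p)
    p
}

#' Simulate read evidence for one junction
#'
#' Split and spanning counts are Poisson with mean proportional to
#' depth x expression; wild-type counts are Poisson with mean proportional
#' to depth. Deterministic under a fixed seed.
#'
#' @param expression relative fusion expression level (0 = not expressed).
#' @param depth mean read depth (> 0).
#' @param seed optional seed; when NULL the current RNG stream is used.
#' @return a \code{ReadEvidence}.
#' @export
simulateReadEvidence <- function(expression = 1, depth = 200, seed = NULL) {
    stopifnot(depth > 0)
    if (!is.null(seed)) set.seed(seed)
    readEvidence(split = stats::rpois(1L, depth * expression * 0.25),
                 spanning = stats::rpois(1L, depth * expression * 0.125),
                 wildtype = stats::rpois(1L, depth * 0.5))
}

# partner pool: gene, canonical tx, candidate junction exons (phase-0 exon
# starts downstream of the start codon), and whether the gene sits within
# FISH resolution of the driver locus
.PARTNER_POOL <- list(
    distant = list(
        BICC1 = list(tx = "NM_001080512.3", exons = 2:4),
        CCDC6 = list(tx = "NM_005436.5", exons = 2:4),
        AFF3  = list(tx = "NM_002285.3", exons = 3:6),
        WAC   = list(tx = "NM_016628.5", exons = 2:3)),
    close = list(
        ATE1  = list(tx = "NM_007041.3", exons = 10:13),
        TACC2 = list(tx = "NM_006997.4", exons = 2:3)),
    bridged = list(
        DBP   = list(tx = "NM_001352.4", exons = 2:4),
        BICC1 = list(tx = "NM_001080512.3", exons = 2:4)))

# dimerisation domain fully retained 3' of a partner junction? (same
# arithmetic the annotator uses: first fully partner-encoded amino acid)
.gtDimerRetained <- function(model, tx, q) {
    d <- model@domains[[tx]]
    if (is.null(d)) return(FALSE)
    firstAa <- q %/% 3L + if (q %% 3L == 0L) 1L else 2L
    any(d$dimerisation & d$aa_start >= firstAa)
}

# precomputed driver-breakpoint context (everything the per-event draw
# needs, as base vectors)
.driverContext <- function(iso) {
    ex <- exons(iso)
    lab <- mcols(ex)$exon_label
    w <- width(ex)
    cum <- cumsum(w)
    aaPos <- function(aa) vapply(aa, function(a)
        transcriptToGenomic(iso, iso@cdsStart - 1L + 3L * a), 1L)
    list(starts = start(ex), ends = end(ex), lab = lab, cum = cum,
         cdsStart = iso@cdsStart,
         i17 = c(end(ex)[lab == "18"] + 1L, start(ex)[lab == "17"] - 1L),
         e17aa = 757:761, e17pos = aaPos(757:761),
         e18aa = 763:768, e18pos = aaPos(763:768))
}

# driver breakpoint draw; returns genomic pos, junction exon5/offset5 and
# retained driver aa (codon-aligned inside coding exons so the transcribed
# junction phase is 0)
.drawDriverBreak <- function(ctx, region) {
    if (region == "intron17") {
        pos <- ctx$i17[1] + sample.int(ctx$i17[2] - ctx$i17[1] + 1L, 1L) - 1L
        list(pos = pos, exon5 = "17", offset5 = 0L, aa = 762L)
    } else if (region == "exon17") {
        k <- sample.int(length(ctx$e17aa), 1L)
        aa <- ctx$e17aa[k]
        cdna <- ctx$cdsStart - 1L + 3L * aa
        list(pos = ctx$e17pos[k], exon5 = "17",
             offset5 = ctx$cum[match("17", ctx$lab)] - cdna, aa = aa)
    } else if (region == "exon18") {
        k <- sample.int(length(ctx$e18aa), 1L)
        aa <- ctx$e18aa[k]
        cdna <- ctx$cdsStart - 1L + 3L * aa
        list(pos = ctx$e18pos[k], exon5 = "18",
             offset5 = ctx$cum[match("18", ctx$lab)] - cdna, aa = aa)
    } else {  # upstream: intron 10..16
        k <- sample(10:16, 1L)
        lo <- ctx$ends[match(as.character(k + 1L), ctx$lab)] + 1L
        hi <- ctx$starts[match(as.character(k), ctx$lab)] - 1L
        list(pos = lo + sample.int(hi - lo + 1L, 1L) - 1L,
             exon5 = as.character(k), offset5 = 0L,
             aa = (ctx$cum[match(as.character(k), ctx$lab)] -
                   ctx$cdsStart + 1L) %/% 3L)
    }
}

#' Simulate a fusion cohort with ground-truth labels
#'
#' Generates matched DNA \code{BreakpointEvent}s and, for expressed events,
#' RNA \code{FusionJunction}s, plus a ground-truth table with the class,
#' frame, mechanism and expression of every event. Reproducible under the
#' seed in \code{params}.
#'
#' @param params a \code{CohortParams}.
#' @param model a \code{GeneModel} containing FGFR2 and the partner genes
#'   (default \code{fusionGeneModel()}).
#' @return list (class \code{"fusionCohort"}) with \code{events},
#'   \code{junctions}, \code{truth} (data.frame) and \code{params}.
#' @export
simulateCohort <- function(params, model = fusionGeneModel()) {
    stopifnot(is(params, "CohortParams"))
    set.seed(params@seed)
    n <- params@nEvents
    empty <- list(events = list(), junctions = list(),
                  truth = data.frame(), params = params)
    class(empty) <- "fusionCohort"
    if (n == 0L) return(empty)

    iso <- canonicalIsoform(model, "FGFR2")
    ctx <- .driverContext(iso)
    # per-partner static context: exon starts/widths, CDS start, chromosome
    pctx <- new.env(parent = emptyenv())
    for (pool in .PARTNER_POOL) for (pp in pool) {
        if (!is.null(pctx[[pp$tx]])) next
        isoP <- getIsoform(model, pp$tx)
        exP <- exons(isoP)
        pctx[[pp$tx]] <- list(chrom = as.character(seqnames(exP))[1],
                              starts = start(exP), widths = width(exP),
                              cdsStart = isoP@cdsStart)
    }
    classes <- sample(c("bridged", "close", "out_of_frame", "deletion_3p",
                        "upstream", "standard"), n, replace = TRUE,
        prob = c(params@pBridged, params@pClosePartner, params@pOutOfFrame,
                 params@p3pDeletion, params@pUpstream,
                 1 - params@pBridged - params@pClosePartner -
                     params@pOutOfFrame - params@p3pDeletion - params@pUpstream))
    w <- params@breakendWeights / sum(params@breakendWeights)

    events <- vector("list", n)
    junctions <- list()
    truth <- vector("list", n)
    ex18 <- exons(iso)[mcols(exons(iso))$exon_label == "18"]

    for (i in seq_len(n)) {
        cls <- classes[i]
        id <- sprintf("ev_%05d", i)
        region <- if (cls == "upstream") "upstream"
                  else sample(names(w), 1L, prob = w)
        dr <- .drawDriverBreak(ctx, region)
        be5 <- breakend("chr10", dr$pos, "right")
        expressed <- cls != "deletion_3p"
        offset3 <- if (cls == "out_of_frame") sample(1:2, 1L) else 0L

        partnerGene <- NA_character_; partnerTx <- NA_character_
        partnerExon <- NA_integer_; q <- NA_integer_
        be3 <- NULL; status <- "mapped"
        ins <- NA_character_; insOrig <- NA_character_
        intergenic <- FALSE

        if (cls == "deletion_3p") {
            be3 <- breakend("chr10", start(ex18) + 50L, "left")
        } else {
            pool <- switch(cls, close = .PARTNER_POOL$close,
                           bridged = .PARTNER_POOL$bridged,
                           .PARTNER_POOL$distant)
            if (cls == "bridged" && stats::runif(1) < 0.30) {
                intergenic <- TRUE
                status <- "intergenic"
                be3 <- breakend("chr10",
                                90000000L + sample.int(6000000L, 1L), "right")
            } else {
                partnerGene <- sample(names(pool), 1L)
                pp <- pool[[partnerGene]]
                partnerTx <- pp$tx
                partnerExon <- sample(pp$exons, 1L)
                pc <- pctx[[partnerTx]]
                pos3 <- if (offset3 > 0L)
                    pc$starts[partnerExon] + offset3
                else pc$starts[partnerExon] - 100L   # intron, splices to exon
                be3 <- breakend(pc$chrom, pos3, "right")
                q <- sum(pc$widths[seq_len(partnerExon - 1L)]) + offset3 -
                    (pc$cdsStart - 1L)
                if (cls == "bridged") {
                    ins <- paste0(rep("GGCCGGGCGCGGTGGCTCAC", 4L), collapse = "")
                    insOrig <- if (stats::runif(1) < 0.5) "repeat:AluSx"
                               else sprintf("chr1:%d", 1000000L + sample.int(1000000L, 1L))
                    status <- "ambiguous"
                }
            }
        }

        expr <- if (expressed) stats::runif(1, 0.5, 1.5) else 0
        ev <- simulateReadEvidence(if (expressed) expr else 0, params@depth)
        events[[i]] <- breakpointEvent(id, be5, be3, partnerStatus = status,
            insertSeq = ins, insertOrigin = insOrig,
            evidence = readEvidence(max(1L, ev@splitReads %/% 4L),
                                    max(1L, ev@spanningPairs %/% 4L),
                                    ev@wildtypeReads %/% 4L))

        if (expressed && !is.na(partnerGene)) {
            junctions[[length(junctions) + 1L]] <- fusionJunction(id,
                "FGFR2", "NM_000141.4", dr$exon5, dr$offset5,
                partnerGene, partnerTx, as.character(partnerExon), offset3,
                evidence = ev)
        } else if (expressed && intergenic) {
            junctions[[length(junctions) + 1L]] <- fusionJunction(id,
                "FGFR2", "NM_000141.4", dr$exon5, dr$offset5,
                "intergenic", "novel", "1", 0L, evidence = ev, novel3 = TRUE)
        }

        # ground-truth labels, by construction
        yldlLost <- TRUE   # all simulated breaks retain < aa 772
        kinase <- region != "upstream"
        frame <- if (cls == "deletion_3p") NA_character_
            else if (intergenic) "indeterminate"
            else if (cls == "out_of_frame") "out_of_frame"
            else "in_frame"
        dimer <- if (!is.na(partnerGene) && frame == "in_frame" &&
                     !is.na(q)) .gtDimerRetained(model, partnerTx, q) else FALSE
        mechanismRna <- if (!kinase) "none"
            else if (cls == "deletion_3p") "c_terminal_truncation"
            else if (intergenic) "indeterminate"
            else if (identical(frame, "in_frame") && dimer) "enhanced_dimerisation"
            else "c_terminal_truncation"
        mechanismDna <- if (!kinase) "none"
            else if (cls == "deletion_3p") "c_terminal_truncation"
            else if (cls == "bridged") "indeterminate"
            else mechanismRna
        truth[[i]] <- data.frame(id = id, class = cls, region5 = region,
            partner_gene = partnerGene, partner_exon = partnerExon,
            frame = frame, mechanism_rna = mechanismRna,
            mechanism_dna = mechanismDna, kinase_retained = kinase,
            expressed = expressed, dimer_retained = dimer,
            stringsAsFactors = FALSE)
    }
    out <- list(events = events, junctions = junctions,
                truth = do.call(rbind, truth), params = params)
    class(out) <- "fusionCohort"
    out
}
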