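## Declarative models of the six diagnostic assay classes and their
## per-event evaluators, plus cohort coverage and the scenario capability
## matrix.

.verdict <- function(assay, eventId, detected, partner, frame, expr, failure)
    new("AssayVerdict", assay = assay, eventId = eventId, detected = detected,
        partnerResolution = partner, frameDeterminable = frame,
        expressionAssessed = expr, failureMode = failure)

.isDeletion <- function(ev, model) {
    if (is.null(ev@breakend3)) return(FALSE)
    g5 <- .geneAt(model, ev@breakend5@chrom, ev@breakend5@pos)
    g3 <- .geneAt(model, ev@breakend3@chrom, ev@breakend3@pos)
    !is.na(g5) && identical(g5, g3)
}

## ---- break-apart FISH ----------------------------------------------------

#' @describeIn evaluateAssay Break-apart FISH: detected when the driver
#'   breakend falls between the two probes and the rearranged partner locus
#'   is separated from the driver probe pair by at least the probe
#'   resolution; close-proximity partners are false negatives; intragenic 3'
#'   deletions are invisible; partner-agnostic and blind to frame and
#'   expression.
setMethod("evaluateAssay", signature(design = "BAFishDesign",
                                     event = "BreakpointEvent"),
    function(design, event, model, ...) {
        b5 <- event@breakend5
        innerLo <- min(end(design@probe3), end(design@probe5)) + 1L
        innerHi <- max(start(design@probe3), start(design@probe5)) - 1L
        chromOK <- b5@chrom %in% c(as.character(seqnames(design@probe5)),
                                   as.character(seqnames(design@probe3)))
        between <- chromOK && b5@pos >= innerLo && b5@pos <= innerHi
        if (!between)
            return(.verdict(design@name, event@id, FALSE, "none", FALSE, FALSE,
                            "not_covered"))
        if (.isDeletion(event, model))
            return(.verdict(design@name, event@id, FALSE, "none", FALSE, FALSE,
                            "not_covered"))
        if (!is.null(event@breakend3)) {
            b3 <- event@breakend3
            sep <- if (b3@chrom != b5@chrom) Inf else abs(b3@pos - b5@pos)
            if (sep < design@resolutionBp)
                return(.verdict(design@name, event@id, FALSE, "none", FALSE,
                                FALSE, "close_proximity"))
        }
        .verdict(design@name, event@id, TRUE, "agnostic_unidentified",
                 FALSE, FALSE, "none")
    })

## ---- dual-fusion FISH ----------------------------------------------------

#' @describeIn evaluateAssay Dual-fusion FISH: detected only when the
#'   partner breakend overlaps the designed partner probe; any other partner
#'   (or none) is a wrong-partner miss; partner resolution is specific.
setMethod("evaluateAssay", signature(design = "DualFishDesign",
                                     event = "BreakpointEvent"),
    function(design, event, model, ...) {
        b3 <- event@breakend3
        hit <- !is.null(b3) &&
            b3@chrom == as.character(seqnames(design@partnerProbe))[1] &&
            b3@pos >= start(design@partnerProbe)[1] &&
            b3@pos <= end(design@partnerProbe)[1] &&
            !.isDeletion(event, model)
        if (hit)
            .verdict(design@name, event@id, TRUE, "specific", FALSE, FALSE,
                     "none")
        else
            .verdict(design@name, event@id, FALSE, "none", FALSE, FALSE,
                     "wrong_partner")
    })

## ---- 5'/3' imbalance -----------------------------------------------------

#' @describeIn evaluateAssay Imbalance assay: compares molecule counts for
#'   the 5' and 3' ends of the driver transcript; detected when the 3'/5'
#'   ratio falls below the threshold. Detects fusions and 3' deletions alike
#'   but cannot distinguish them, identify a partner or determine frame.
#' @param expression numeric length-2 vector \code{c(count5, count3)} of
#'   simulated molecule counts (imbalance assay only).
setMethod("evaluateAssay", signature(design = "ImbalanceDesign", event = "ANY"),
    function(design, event, model, ..., expression) {
        stopifnot(length(expression) == 2L, expression[1] > 0)
        ratio <- expression[2] / expression[1]
        id <- if (is(event, "BreakpointEvent") || is(event, "FusionJunction"))
            event@id else "none"
        if (ratio < design@ratioThreshold)
            .verdict(design@name, id, TRUE, "none", FALSE, TRUE, "none")
        else
            .verdict(design@name, id, FALSE, "none", FALSE, TRUE,
                     "below_threshold")
    })

## ---- amplicon ------------------------------------------------------------

#' @describeIn evaluateAssay Amplicon panel (closed design): detected only
#'   when the driver-side exon carries a primer and the partner gene and its
#'   junction exon are both in the panel; unknown or intergenic partners can
#'   never be detected.
setMethod("evaluateAssay", signature(design = "AmpliconDesign",
                                     event = "FusionJunction"),
    function(design, event, model, ...) {
        if (!event@exon5 %in% design@driverPrimers)
            return(.verdict(design@name, event@id, FALSE, "none", FALSE, FALSE,
                            "not_covered"))
        pset <- design@partnerPrimers[[event@gene3]]
        if (is.null(pset) || !event@exon3 %in% pset)
            return(.verdict(design@name, event@id, FALSE, "none", FALSE, FALSE,
                            "partner_not_in_design"))
        .verdict(design@name, event@id, TRUE, "specific", TRUE, TRUE, "none")
    })

## ---- single-primer extension ---------------------------------------------

#' @describeIn evaluateAssay SPE / anchored multiplex PCR (open design): one
#'   gene-specific primer on the driver junction exon suffices, so detection
#'   is partner-agnostic with the partner identified from the read sequence;
#'   junction exons absent from the design isoform (panels are designed on
#'   the canonical transcript) are not covered.
setMethod("evaluateAssay", signature(design = "SPEDesign",
                                     event = "FusionJunction"),
    function(design, event, model, ...) {
        iso <- model@isoforms[[design@designIsoform]]
        onIso <- !is.null(iso) &&
            event@exon5 %in% mcols(iso@exons)$exon_label
        if (!onIso || !event@exon5 %in% design@driverPrimers)
            return(.verdict(design@name, event@id, FALSE, "none", FALSE, FALSE,
                            "not_covered"))
        .verdict(design@name, event@id, TRUE, "agnostic_identified", TRUE,
                 TRUE, "none")
    })

## ---- hybrid capture ------------------------------------------------------

.hycaDnaPartner <- function(event, model) {
    # bridged inserts that map to a third locus or only to repeat families
    # leave the partner unresolved; the event is still reported, as a
    # rearrangement rather than a fusion
    if (!is.na(event@insertSeq) && nchar(event@insertSeq) >= 10L &&
        !is.na(event@insertOrigin))
        return(list(partner = "agnostic_unidentified",
                    failure = "bridged_unresolved"))
    if (is.null(event@breakend3) ||
        event@partnerStatus %in% c("unmapped", "ambiguous"))
        return(list(partner = "agnostic_unidentified",
                    failure = "bridged_unresolved"))
    g3 <- .geneAt(model, event@breakend3@chrom, event@breakend3@pos)
    if (is.na(g3))   # intergenic: rearrangement with no partner gene
        return(list(partner = "agnostic_unidentified", failure = "none"))
    list(partner = "agnostic_identified", failure = "none")
}

#' @describeIn evaluateAssay Hybrid capture: at DNA level, detected when the
#'   driver breakend lies in a probe-tiled interval (intron 17 must be tiled
#'   in its entire length); the partner is identified only when the non-driver
#'   side maps uniquely within an annotated gene — bridged inserts and
#'   repeat-only alignments leave a detected but unresolved rearrangement.
#'   At RNA level every expressed junction whose driver exon is captured is
#'   detected, with frame determinable and expression assessed.
setMethod("evaluateAssay", signature(design = "HyCaDesign", event = "ANY"),
    function(design, event, model, ...) {
        if (design@level == "DNA") {
            stopifnot(is(event, "BreakpointEvent"))
            b5 <- event@breakend5
            inProbe <- any(as.character(seqnames(design@probes)) == b5@chrom &
                           start(design@probes) <= b5@pos &
                           end(design@probes) >= b5@pos)
            if (!inProbe)
                return(.verdict(design@name, event@id, FALSE, "none", FALSE,
                                FALSE, "not_covered"))
            p <- .hycaDnaPartner(event, model)
            .verdict(design@name, event@id, TRUE, p$partner, FALSE, FALSE,
                     p$failure)
        } else {
            stopifnot(is(event, "FusionJunction"))
            cap <- design@capturedExons[[event@gene5]]
            if (is.null(cap) || !event@exon5 %in% cap)
                return(.verdict(design@name, event@id, FALSE, "none", FALSE,
                                FALSE, "not_covered"))
            .verdict(design@name, event@id, TRUE, "agnostic_identified", TRUE,
                     TRUE, "none")
        }
    })

## ---- design constructors and bundled defaults ----------------------------

#' Bundled default assay designs
#'
#' One design per assay class, configured for the packaged FGFR2 model:
#' break-apart FISH probes flanking the locus with 1 Mb resolution (a
#' conservative interphase separation scale), a BICC1 dual-fusion probe set,
#' a 5'/3' imbalance assay with ratio threshold 0.5, an amplicon panel with
#' driver primers on exons 17/18 and partner primers for a handful of
#' recurrent partners (CCDC6 exons 1-2 among them), an SPE panel designed on
#' NM_000141.4, and hybrid-capture designs tiling exon 17 through exon 18 at
#' DNA level and capturing every described driver exon at RNA level.
#'
#' @param model a \code{GeneModel} (default \code{fusionGeneModel()}).
#' @return named list of \code{AssayDesign} objects.
#' @export
bundledAssayDesigns <- function(model = fusionGeneModel()) {
    locus <- model@genes["FGFR2"]
    chrom <- as.character(seqnames(locus))
    iso <- canonicalIsoform(model, "FGFR2")

    ba <- new("BAFishDesign", name = "BA-FISH",
        probe5 = GRanges(chrom, IRanges(end(locus) + 2000L, end(locus) + 52000L)),
        probe3 = GRanges(chrom, IRanges(start(locus) - 52000L, start(locus) - 2000L)),
        resolutionBp = 1e6)

    dual <- new("DualFishDesign", name = "Dual-FISH", partnerGene = "BICC1",
        partnerProbe = if ("BICC1" %in% names(model@genes))
            granges(model@genes["BICC1"]) else GRanges(chrom, IRanges(1, 2)),
        driverProbe = granges(locus))

    imb <- new("ImbalanceDesign", name = "Imbalance",
        exons5p = as.character(1:8), exons3p = c("17", "18"),
        ratioThreshold = 0.5)

    amp <- new("AmpliconDesign", name = "AMP",
        driverPrimers = c("17", "18"),
        partnerPrimers = list(CCDC6 = c("1", "2"), BICC1 = c("2", "3"),
                              TACC2 = c("2", "3"), ATE1 = c("2", "12"),
                              AFF3 = c("5")))

    spe <- new("SPEDesign", name = "SPE",
        driverPrimers = c("2", "5", "8", "17", "18"),
        designIsoform = "NM_000141.4")

    # DNA tiling: exon 17 through exon 18 including intron 17 end to end
    ex <- exons(iso)
    lab <- mcols(ex)$exon_label
    tile <- range(c(ex[lab == "17"], ex[lab == "18"]), ignore.strand = TRUE)
    hycaDna <- new("HyCaDesign", name = "HyCa-DNA", level = "DNA",
                   probes = tile)

    allDriverExons <- unique(unlist(lapply(geneIsoforms(model, "FGFR2"),
        function(i) mcols(i@exons)$exon_label)))
    hycaRna <- new("HyCaDesign", name = "HyCa-RNA", level = "RNA",
                   capturedExons = list(FGFR2 = allDriverExons))

    list(ba_fish = ba, dual_fish = dual, imbalance = imb, amplicon = amp,
         spe = spe, hyca_dna = hycaDna, hyca_rna = hycaRna)
}

#' @importFrom GenomicRanges granges
NULL

## ---- design config I/O ---------------------------------------------------

.grFromCfg <- function(x) GRanges(x$chrom, IRanges(as.integer(x$start),
                                                   as.integer(x$end)))
.grToCfg <- function(g) list(chrom = as.character(seqnames(g))[1],
                             start = start(g)[1], end = end(g)[1])

#' Read assay designs from YAML or JSON config
#'
#' The config is a named list of design blocks, each with a \code{type}
#' field (\code{ba_fish}, \code{dual_fish}, \code{imbalance},
#' \code{amplicon}, \code{spe}, \code{hyca}) and type-specific fields
#' mirroring the design class slots (intervals as
#' \code{\{chrom, start, end\}} blocks).
#'
#' @param path YAML (.yaml/.yml) or JSON file.
#' @return named list of \code{AssayDesign} objects.
#' @export
readAssayDesigns <- function(path) {
    cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
           else jsonlite::fromJSON(path, simplifyVector = FALSE)
    out <- list()
    for (nm in names(cfg)) {
        d <- cfg[[nm]]
        dName <- if (is.null(d$name)) nm else d$name
        out[[nm]] <- switch(d$type,
            ba_fish = new("BAFishDesign", name = dName,
                probe5 = .grFromCfg(d$probe5), probe3 = .grFromCfg(d$probe3),
                resolutionBp = as.numeric(d$resolution_bp)),
            dual_fish = new("DualFishDesign", name = dName,
                partnerGene = d$partner_gene,
                partnerProbe = .grFromCfg(d$partner_probe),
                driverProbe = .grFromCfg(d$driver_probe)),
            imbalance = new("ImbalanceDesign", name = dName,
                exons5p = as.character(unlist(d$exons_5p)),
                exons3p = as.character(unlist(d$exons_3p)),
                ratioThreshold = as.numeric(d$ratio_threshold)),
            amplicon = new("AmpliconDesign", name = dName,
                driverPrimers = as.character(unlist(d$driver_primers)),
                partnerPrimers = lapply(d$partner_primers,
                                        function(x) as.character(unlist(x)))),
            spe = new("SPEDesign", name = dName,
                driverPrimers = as.character(unlist(d$driver_primers)),
                designIsoform = d$design_isoform),
            hyca = if (identical(d$level, "DNA"))
                new("HyCaDesign", name = dName, level = "DNA",
                    probes = do.call(c, lapply(d$probes, .grFromCfg)))
            else
                new("HyCaDesign", name = dName, level = "RNA",
                    capturedExons = lapply(d$captured_exons,
                                           function(x) as.character(unlist(x)))),
            stop("unknown assay design type: ", d$type))
    }
    out
}

#' Export the probe tiling of a DNA hybrid-capture design as BED
#' @param design a DNA-level \code{HyCaDesign}.
#' @param path output BED path (0-based half-open).
#' @export
writeProbesBed <- function(design, path) {
    stopifnot(is(design, "HyCaDesign"), design@level == "DNA")
    rows <- sprintf("%s\t%d\t%d\t%s", as.character(seqnames(design@probes)),
                    start(design@probes) - 1L, end(design@probes),
                    design@name)
    writeLines(rows, path)
    invisible(path)
}

## ---- cohort coverage and scenario matrix ---------------------------------

.assayInput <- function(design, evDNA, evRNA) {
    if (is(design, "BAFishDesign") || is(design, "DualFishDesign") ||
        (is(design, "HyCaDesign") && design@level == "DNA")) evDNA
    else evRNA
}

# imbalance molecule counts for one cohort member: fusion transcripts lose
# the driver 3' exons, so the 3' count collapses onto wild-type molecules
.imbalanceCounts <- function(evidence) {
    k <- readCounts(evidence)
    c(max(1L, sum(k)), k[["wildtype"]])
}

#' Detected fraction per assay design over a cohort
#'
#' Each design is evaluated on the representation it consumes: FISH and
#' DNA-level hybrid capture see the \code{BreakpointEvent}, RNA assays see
#' the matched \code{FusionJunction}; events without an expressed junction
#' are undetectable by RNA assays. The imbalance assay derives its 5'/3'
#' molecule counts from the junction read evidence (all molecules versus
#' wild-type-only molecules).
#'
#' @param cohort a simulated cohort (from \code{simulateCohort}) or a plain
#'   list of \code{BreakpointEvent}/\code{FusionJunction} objects.
#' @param designs list of \code{AssayDesign}.
#' @param model a \code{GeneModel}.
#' @return list with \code{fractions} (named numeric) and \code{verdicts}
#'   (data.frame event x design of logicals) and \code{details} (nested list
#'   of \code{AssayVerdict}).
#' @export
cohortCoverage <- function(cohort, designs, model) {
    if (is.list(cohort) && !is.null(cohort$events)) {
        events <- cohort$events
        junctions <- cohort$junctions
        jIds <- vapply(junctions, function(j) j@id, "")
        members <- lapply(events, function(ev) {
            jm <- match(ev@id, jIds)
            list(id = ev@id, dna = ev,
                 rna = if (is.na(jm)) NULL else junctions[[jm]])
        })
    } else {
        if (length(cohort) == 0L) stop("empty cohort")
        members <- lapply(cohort, function(x)
            list(id = x@id,
                 dna = if (is(x, "BreakpointEvent")) x else NULL,
                 rna = if (is(x, "FusionJunction")) x else NULL))
    }
    if (length(members) == 0L) stop("empty cohort")
    details <- list()
    det <- matrix(FALSE, nrow = length(members), ncol = length(designs),
                  dimnames = list(vapply(members, `[[`, "", "id"),
                                  names(designs)))
    for (dn in names(designs)) {
        design <- designs[[dn]]
        vl <- vector("list", length(members))
        for (i in seq_along(members)) {
            m <- members[[i]]
            input <- .assayInput(design, m$dna, m$rna)
            v <- if (is.null(input))
                .verdict(design@name, m$id, FALSE, "none", FALSE, FALSE,
                         "not_covered")
            else if (is(design, "ImbalanceDesign"))
                evaluateAssay(design, input, model,
                              expression = .imbalanceCounts(input@evidence))
            else evaluateAssay(design, input, model)
            vl[[i]] <- v
            det[i, dn] <- v@detected
        }
        details[[dn]] <- vl
    }
    list(fractions = colMeans(det), verdicts = as.data.frame(det),
         details = details)
}

#' Scenario capability matrix across the six assay classes
#'
#' Builds the canonical scenario set — wild-type, known partner, unknown
#' partner, out-of-frame fusion, intergenic rearrangement, close-proximity
#' partner, and intragenic 3' deletion — on the packaged model and evaluates
#' every design on each. The wild-type row is the negative control and must
#' be not-detected everywhere.
#'
#' @param designs list of \code{AssayDesign} (default bundled set).
#' @param model a \code{GeneModel}.
#' @return list with \code{matrix} (data.frame scenario x design of
#'   logicals) and \code{verdicts} (nested list).
#' @export
capabilityMatrix <- function(designs = NULL, model = fusionGeneModel()) {
    if (is.null(designs)) designs <- bundledAssayDesigns(model)
    iso <- canonicalIsoform(model, "FGFR2")
    ex <- exons(iso)
    lab <- mcols(ex)$exon_label
    i17 <- end(ex[lab == "18"]) + 2000L   # inside intron 17 (minus strand)
    ev <- function(id, chrom3, pos3, status = "mapped",
                   ins = NA_character_, insOrig = NA_character_)
        breakpointEvent(id, breakend("chr10", i17, "right"),
            if (is.null(chrom3)) NULL else breakend(chrom3, pos3, "left"),
            partnerStatus = status, insertSeq = ins, insertOrigin = insOrig,
            evidence = readEvidence(20, 10, 30))
    jn <- function(id, gene3, tx3, exon3, off3 = 0L, novel3 = FALSE)
        fusionJunction(id, "FGFR2", "NM_000141.4", "17", 0L, gene3, tx3,
                       exon3, off3, evidence = readEvidence(25, 10, 20),
                       novel3 = novel3)
    locus <- function(g) if (g %in% names(model@genes))
        start(model@genes[g]) + 10000L else NA

    scen <- list(
        wildtype = list(dna = NULL, rna = NULL, imb = c(100, 100)),
        known_partner = list(dna = ev("sc_known", "chr10", locus("BICC1")),
            rna = jn("sc_known", "BICC1", "NM_001080512.3", "3"),
            imb = c(100, 20)),
        unknown_partner = list(dna = ev("sc_unknown", "chr10", 90000000L),
            rna = jn("sc_unknown", "NOVELGENE", "unknown", "2", novel3 = TRUE),
            imb = c(100, 20)),
        out_of_frame = list(dna = ev("sc_oof", "chr10", locus("BICC1")),
            rna = jn("sc_oof", "BICC1", "NM_001080512.3", "3", off3 = 1L),
            imb = c(100, 20)),
        intergenic = list(dna = ev("sc_inter", "chr10", 95000000L,
                                   status = "intergenic"),
            rna = jn("sc_inter", "intergenic", "none", "NA", novel3 = TRUE),
            imb = c(100, 20)),
        close_partner = list(dna = ev("sc_close", "chr10", locus("ATE1")),
            rna = jn("sc_close", "ATE1", "NM_007041.3", "12"),
            imb = c(100, 20)),
        deletion_3p = list(
            dna = breakpointEvent("sc_del", breakend("chr10", i17, "right"),
                breakend("chr10", start(ex[lab == "18"]) + 20L, "left"),
                evidence = readEvidence(15, 5, 40)),
            rna = jn("sc_del", "readthrough", "none", "NA", novel3 = TRUE),
            imb = c(100, 5)))

    mat <- matrix(FALSE, nrow = length(scen), ncol = length(designs),
                  dimnames = list(names(scen), names(designs)))
    verdicts <- list()
    for (sn in names(scen)) {
        s <- scen[[sn]]
        verdicts[[sn]] <- list()
        for (dn in names(designs)) {
            design <- designs[[dn]]
            input <- .assayInput(design, s$dna, s$rna)
            v <- if (is(design, "ImbalanceDesign"))
                evaluateAssay(design, if (is.null(s$rna)) s$dna else s$rna,
                              model, expression = s$imb)
            else if (is.null(input))
                .verdict(design@name, sn, FALSE, "none", FALSE, FALSE,
                         "below_threshold")
            else evaluateAssay(design, input, model)
            verdicts[[sn]][[dn]] <- v
            mat[sn, dn] <- v@detected
        }
    }
    list(matrix = as.data.frame(mat), verdicts = verdicts)
}
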