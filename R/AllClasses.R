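#' @import methods
#' @importClassesFrom Biostrings DNAString
#' @importFrom S4Vectors mcols mcols<- DataFrame
#' @importFrom GenomicRanges GRanges seqnames start end strand width
#' @importFrom IRanges IRanges
NULL

setClassUnion("DNAStringOrNULL", c("DNAString", "NULL"))

#' TranscriptIsoform: one transcript model
#'
#' Ordered exon/CDS structure of a single transcript. Exons are stored as a
#' \code{GRanges} in transcript order (5' to 3' of the mRNA; genomic
#' coordinates decrease along the list for minus-strand genes), with metadata
#' columns \code{exon_label} (display label, parent-relative for FGFR2
#' isoforms) and \code{exon_rank} (local 1-based index). CDS bounds are
#' 1-based transcript (cDNA) coordinates and include the stop codon.
#'
#' @slot transcriptId RefSeq-style accession.
#' @slot gene gene symbol.
#' @slot exons \code{GRanges} of exons in transcript order.
#' @slot cdsStart,cdsEnd 1-based cDNA bounds of the CDS (NA if non-coding).
#' @slot sequence optional \code{DNAString} of the spliced transcript.
#' @exportClass TranscriptIsoform
setClass("TranscriptIsoform",
    representation(
        transcriptId = "character",
        gene         = "character",
        exons        = "GRanges",
        cdsStart     = "integer",
        cdsEnd       = "integer",
        sequence     = "DNAStringOrNULL"
    ),
    prototype(cdsStart = NA_integer_, cdsEnd = NA_integer_, sequence = NULL)
)

setValidity("TranscriptIsoform", function(object) {
    ex <- object@exons
    msg <- character()
    if (length(ex) == 0L)
        msg <- c(msg, "isoform must have at least one exon")
    if (length(ex) > 0L) {
        str <- unique(as.character(strand(ex)))
        if (length(str) != 1L || !str %in% c("+", "-"))
            msg <- c(msg, "exons must share a single strand ('+' or '-')")
        if (length(unique(as.character(seqnames(ex)))) != 1L)
            msg <- c(msg, "exons must lie on a single chromosome")
        if (length(ex) > 1L) {
            s <- start(ex)
            ordOK <- if (identical(str, "-")) all(diff(s) < 0) else all(diff(s) > 0)
            if (!isTRUE(ordOK))
                msg <- c(msg, "exons not in transcript order consistent with strand")
            red <- GenomicRanges::reduce(sort(ex))
            if (sum(width(red)) != sum(width(ex)))
                msg <- c(msg, "exons overlap")
        }
    }
    if (!is.na(object@cdsStart)) {
        len <- object@cdsEnd - object@cdsStart + 1L
        if (len %% 3L != 0L)
            msg <- c(msg, sprintf("CDS length %d not divisible by 3", len))
        if (object@cdsEnd > sum(width(ex)))
            msg <- c(msg, "CDS end beyond spliced transcript length")
    }
    if (length(msg)) msg else TRUE
})

#' GeneModel: a bundle of gene loci, isoforms and protein domains
#'
#' @slot genes named \code{GRanges} of gene loci (names = gene symbols).
#' @slot isoforms named list of \code{TranscriptIsoform}.
#' @slot domains named list (by transcript id) of data.frames with columns
#'   \code{name}, \code{aa_start}, \code{aa_end}, \code{dimerisation}.
#' @slot build genome build label, e.g. \code{"hg19"}.
#' @slot altRegions \code{GRanges} of additional described exonic regions not
#'   belonging to any bundled isoform (used for the exonic-region catalog).
#' @exportClass GeneModel
setClass("GeneModel",
    representation(
        genes      = "GRanges",
        isoforms   = "list",
        domains    = "list",
        build      = "character",
        altRegions = "GRanges"
    ),
    prototype(build = "custom", altRegions = GRanges())
)

setValidity("GeneModel", function(object) {
    msg <- character()
    if (is.null(names(object@genes)) && length(object@genes) > 0L)
        msg <- c(msg, "gene loci must be named by symbol")
    for (iso in object@isoforms) {
        if (!is(iso, "TranscriptIsoform")) {
            msg <- c(msg, "isoforms must be TranscriptIsoform objects")
            next
        }
        if (!iso@gene %in% names(object@genes)) {
            msg <- c(msg, sprintf("isoform %s references unknown gene %s",
                                  iso@transcriptId, iso@gene))
            next
        }
        locus <- object@genes[iso@gene]
        ex <- iso@exons
        if (!all(as.character(seqnames(ex)) == as.character(seqnames(locus))) ||
            any(start(ex) < start(locus)) || any(end(ex) > end(locus)))
            msg <- c(msg, sprintf("exons of %s fall outside the %s locus",
                                  iso@transcriptId, iso@gene))
    }
    bad <- setdiff(names(object@domains), names(object@isoforms))
    if (length(bad))
        msg <- c(msg, sprintf("domains reference unknown isoform(s): %s",
                              paste(bad, collapse = ", ")))
    if (length(msg)) msg else TRUE
})

#' ReadEvidence: read support at a junction or breakpoint
#' @slot splitReads,spanningPairs,wildtypeReads non-negative counts.
#' @exportClass ReadEvidence
setClass("ReadEvidence",
    representation(splitReads = "integer", spanningPairs = "integer",
                   wildtypeReads = "integer"),
    prototype(splitReads = 0L, spanningPairs = 0L, wildtypeReads = 0L)
)

setValidity("ReadEvidence", function(object) {
    counts <- c(object@splitReads, object@spanningPairs, object@wildtypeReads)
    if (any(is.na(counts)) || any(counts < 0L))
        "read counts must be non-negative" else TRUE
})

#' Breakend: one side of a DNA rearrangement
#'
#' \code{orientation} records which genomic side of the position stays joined
#' to the partner: \code{"left"} means bases at or below \code{pos} are
#' retained, \code{"right"} means bases at or above \code{pos} are retained.
#' For the minus-strand FGFR2 driver the transcript-upstream (kinase-encoding)
#' portion is the genomic right side.
#'
#' @slot chrom chromosome name.
#' @slot pos 1-based breakpoint base (last retained base on the retained side).
#' @slot orientation \code{"left"} or \code{"right"}.
#' @exportClass Breakend
setClass("Breakend",
    representation(chrom = "character", pos = "integer", orientation = "character")
)

setValidity("Breakend", function(object) {
    msg <- character()
    if (!object@orientation %in% c("left", "right"))
        msg <- c(msg, "orientation must be 'left' or 'right'")
    if (is.na(object@pos) || object@pos < 1L)
        msg <- c(msg, "pos must be a positive base position")
    if (length(msg)) msg else TRUE
})

setClassUnion("BreakendOrNULL", c("Breakend", "NULL"))

#' BreakpointEvent: a DNA-level rearrangement
#'
#' @slot id stable event identifier.
#' @slot breakend5 driver-side (FGFR2) breakend.
#' @slot breakend3 partner-side breakend, or NULL when unmapped.
#' @slot partnerStatus one of \code{"mapped"}, \code{"unmapped"},
#'   \code{"intergenic"}, \code{"ambiguous"}.
#' @slot insertSeq optional bridging insert sequence (NA if none).
#' @slot insertOrigin optional mapped origin of the insert, either a
#'   \code{"chrN:pos"} locus or a \code{"repeat:<family>"} tag.
#' @slot evidence \code{ReadEvidence}.
#' @exportClass BreakpointEvent
setClass("BreakpointEvent",
    representation(
        id            = "character",
        breakend5     = "Breakend",
        breakend3     = "BreakendOrNULL",
        partnerStatus = "character",
        insertSeq     = "character",
        insertOrigin  = "character",
        evidence      = "ReadEvidence"
    ),
    prototype(breakend3 = NULL, partnerStatus = "mapped",
              insertSeq = NA_character_, insertOrigin = NA_character_)
)

setValidity("BreakpointEvent", function(object) {
    msg <- character()
    if (!object@partnerStatus %in% c("mapped", "unmapped", "intergenic", "ambiguous"))
        msg <- c(msg, "invalid partnerStatus")
    if (identical(object@partnerStatus, "mapped") && is.null(object@breakend3))
        msg <- c(msg, "mapped partner requires breakend3")
    if (!is.na(object@insertOrigin) && !is.null(object@breakend3) &&
        !grepl("^repeat:", object@insertOrigin)) {
        o5 <- paste0(object@breakend5@chrom, ":", object@breakend5@pos)
        o3 <- paste0(object@breakend3@chrom, ":", object@breakend3@pos)
        if (object@insertOrigin %in% c(o5, o3))
            msg <- c(msg, "insert origin must differ from both breakend loci")
    }
    if (length(msg)) msg else TRUE
})

#' FusionJunction: an RNA-level fusion junction
#'
#' Each side is addressed as exon label plus an offset in nucleotides from the
#' exon boundary nearest the junction: on the 5' side \code{offset5} is the
#' number of bases trimmed from the 3' end of exon \code{exon5} (0 = junction
#' exactly after the full exon); on the 3' side \code{offset3} is the number
#' of bases skipped from the 5' start of exon \code{exon3}.
#'
#' @slot id identifier.
#' @slot gene5,tx5,exon5,offset5 driver side (gene, transcript, exon label, offset).
#' @slot gene3,tx3,exon3,offset3 partner side.
#' @slot novel5,novel3 TRUE when the transcript id is absent from the model.
#' @slot evidence \code{ReadEvidence}.
#' @exportClass FusionJunction
setClass("FusionJunction",
    representation(
        id = "character",
        gene5 = "character", tx5 = "character", exon5 = "character", offset5 = "integer",
        gene3 = "character", tx3 = "character", exon3 = "character", offset3 = "integer",
        novel5 = "logical", novel3 = "logical",
        evidence = "ReadEvidence"
    ),
    prototype(novel5 = FALSE, novel3 = FALSE, offset5 = 0L, offset3 = 0L)
)

setValidity("FusionJunction", function(object) {
    if (is.na(object@offset5) || is.na(object@offset3) ||
        object@offset5 < 0L || object@offset3 < 0L)
        "junction offsets must be >= 0" else TRUE
})

#' FusionAnnotation: per-isoform interpretation of one event
#'
#' @slot eventId event identifier.
#' @slot records data.frame, one row per driver-isoform x partner-isoform
#'   pair, with columns \code{isoform5}, \code{isoform3}, \code{region5},
#'   \code{region3}, \code{cdna5}, \code{frame}, \code{kinase_retained},
#'   \code{kinase_warning}, \code{mechanism}, \code{competent},
#'   \code{lost_motifs}, \code{grb2_site_lost}, \code{retained_partner_domains}.
#' @slot conflict TRUE when isoforms disagree on frame or mechanism.
#' @exportClass FusionAnnotation
setClass("FusionAnnotation",
    representation(eventId = "character", records = "data.frame",
                   conflict = "logical")
)

## ---- assay designs -------------------------------------------------------

#' Virtual parent of the six assay design classes
#' @exportClass AssayDesign
setClass("AssayDesign", representation("VIRTUAL", name = "character"))

#' Break-apart FISH design (two probes flanking the driver locus)
#' @slot probe5,probe3 probe footprints as \code{GRanges}.
#' @slot resolutionBp minimum genomic separation resolvable in interphase nuclei.
#' @exportClass BAFishDesign
setClass("BAFishDesign", contains = "AssayDesign",
    representation(probe5 = "GRanges", probe3 = "GRanges", resolutionBp = "numeric"))

#' Dual-fusion FISH design (driver probe + one partner-specific probe)
#' @slot partnerGene designed partner gene symbol.
#' @slot partnerProbe,driverProbe probe footprints.
#' @exportClass DualFishDesign
setClass("DualFishDesign", contains = "AssayDesign",
    representation(partnerGene = "character", partnerProbe = "GRanges",
                   driverProbe = "GRanges"))

#' 5'/3' expression imbalance design
#' @slot exons5p,exons3p exon labels counted for the 5' and 3' ends.
#' @slot ratioThreshold call a rearrangement when 3'/5' molecule ratio falls below this.
#' @exportClass ImbalanceDesign
setClass("ImbalanceDesign", contains = "AssayDesign",
    representation(exons5p = "character", exons3p = "character",
                   ratioThreshold = "numeric"))

#' Amplicon (closed primer-pair) RNA panel design
#' @slot driverPrimers driver exon labels carrying a primer.
#' @slot partnerPrimers named list: gene symbol -> character vector of exon labels.
#' @exportClass AmpliconDesign
setClass("AmpliconDesign", contains = "AssayDesign",
    representation(driverPrimers = "character", partnerPrimers = "list"))

#' Single-primer-extension (anchored multiplex PCR) RNA panel design
#' @slot driverPrimers driver exon labels carrying the gene-specific primer,
#'   as mapped on \code{designIsoform}.
#' @slot designIsoform transcript the primers were designed against.
#' @exportClass SPEDesign
setClass("SPEDesign", contains = "AssayDesign",
    representation(driverPrimers = "character", designIsoform = "character"))

#' Hybrid-capture design (DNA probe tiling or RNA exon capture)
#' @slot level \code{"DNA"} or \code{"RNA"}.
#' @slot probes DNA level: \code{GRanges} of tiled probe intervals.
#' @slot capturedExons RNA level: named list gene -> captured exon labels.
#' @exportClass HyCaDesign
setClass("HyCaDesign", contains = "AssayDesign",
    representation(level = "character", probes = "GRanges", capturedExons = "list"),
    prototype(probes = GRanges(), capturedExons = list()))

setValidity("HyCaDesign", function(object) {
    if (!object@level %in% c("DNA", "RNA")) "level must be 'DNA' or 'RNA'" else TRUE
})

#' AssayVerdict: per-event, per-assay outcome
#'
#' @slot assay assay design name.
#' @slot eventId event identifier.
#' @slot detected would the assay flag this event?
#' @slot partnerResolution one of \code{"specific"}, \code{"agnostic_identified"},
#'   \code{"agnostic_unidentified"}, \code{"none"}.
#' @slot frameDeterminable can the assay decide the reading frame?
#' @slot expressionAssessed does the assay demonstrate expression?
#' @slot failureMode one of \code{"none"}, \code{"not_covered"},
#'   \code{"close_proximity"}, \code{"partner_not_in_design"},
#'   \code{"bridged_unresolved"}, \code{"below_threshold"}, \code{"wrong_partner"}.
#' @exportClass AssayVerdict
setClass("AssayVerdict",
    representation(assay = "character", eventId = "character",
                   detected = "logical", partnerResolution = "character",
                   frameDeterminable = "logical", expressionAssessed = "logical",
                   failureMode = "character"))

setValidity("AssayVerdict", function(object) {
    msg <- character()
    if (!object@partnerResolution %in%
        c("specific", "agnostic_identified", "agnostic_unidentified", "none"))
        msg <- c(msg, "invalid partnerResolution")
    if (!object@failureMode %in%
        c("none", "not_covered", "close_proximity", "partner_not_in_design",
          "bridged_unresolved", "below_threshold", "wrong_partner"))
        msg <- c(msg, "invalid failureMode")
    if (!object@detected && identical(object@failureMode, "none"))
        msg <- c(msg, "undetected verdicts must carry a failure mode")
    if (length(msg)) msg else TRUE
})

#' CohortParams: parameters of the synthetic fusion cohort
#'
#' Defaults encode the published FGFR2 fusion architecture in intrahepatic
#' cholangiocarcinoma: breakpoints concentrated in exon 17 / intron 17 /
#' exon 18 with intron 17 dominant, ~10\% bridged or partnerless
#' rearrangements at DNA level, ~4.2\% partners in close genomic proximity
#' to FGFR2, plus occasional 3' deletions and out-of-frame events.
#'
#' @slot nEvents number of events to simulate.
#' @slot seed RNG seed.
#' @slot pBridged fraction of bridged/intergenic partnerless events.
#' @slot pClosePartner fraction with a partner within FISH resolution.
#' @slot pOutOfFrame fraction of out-of-frame junctions.
#' @slot p3pDeletion fraction of intragenic 3' deletions.
#' @slot pUpstream fraction of non-competent events upstream of exon 17.
#' @slot breakendWeights named weights over \code{exon17}, \code{intron17},
#'   \code{exon18}.
#' @slot depth mean read depth for simulated evidence.
#' @exportClass CohortParams
setClass("CohortParams",
    representation(nEvents = "integer", seed = "integer",
                   pBridged = "numeric", pClosePartner = "numeric",
                   pOutOfFrame = "numeric", p3pDeletion = "numeric",
                   pUpstream = "numeric", breakendWeights = "numeric",
                   depth = "numeric"))

setValidity("CohortParams", function(object) {
    msg <- character()
    p <- c(object@pBridged, object@pClosePartner, object@pOutOfFrame,
           object@p3pDeletion, object@pUpstream)
    if (any(p < 0) || any(p > 1))
        msg <- c(msg, "class fractions must lie in [0,1]")
    if (sum(p) > 1)
        msg <- c(msg, sprintf("class fractions sum to %.3f > 1", sum(p)))
    w <- object@breakendWeights
    if (!all(c("exon17", "intron17", "exon18") %in% names(w)))
        msg <- c(msg, "breakendWeights must name exon17, intron17, exon18")
    if (any(w < 0) || sum(w) <= 0)
        msg <- c(msg, "breakendWeights must be non-negative and sum > 0")
    if (object@nEvents < 0L) msg <- c(msg, "nEvents must be >= 0")
    if (length(msg)) msg else TRUE
})

#' ClinicalReport: a rendered clinical fusion/translocation report
#'
#' @slot level \code{"RNA"} or \code{"DNA"}.
#' @slot fields named list of the machine-readable report content.
#' @slot markdown character vector of rendered Markdown lines.
#' @exportClass ClinicalReport
setClass("ClinicalReport",
    representation(level = "character", fields = "list", markdown = "character"))

setValidity("ClinicalReport", function(object) {
    if (!object@level %in% c("RNA", "DNA")) "level must be 'RNA' or 'DNA'" else TRUE
})
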