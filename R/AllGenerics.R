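## Generics and accessors. Accessor functions are the supported interface;
## slots are internal.

#' @rdname TranscriptIsoform-class
#' @param object a \code{TranscriptIsoform}.
#' @export
setGeneric("transcriptId", function(object) standardGeneric("transcriptId"))
#' @rdname TranscriptIsoform-class
#' @export
setGeneric("geneSymbol", function(object) standardGeneric("geneSymbol"))
#' @rdname TranscriptIsoform-class
#' @export
setGeneric("exons", function(object) standardGeneric("exons"))
#' @rdname TranscriptIsoform-class
#' @export
setGeneric("cdsBounds", function(object) standardGeneric("cdsBounds"))
#' @rdname TranscriptIsoform-class
#' @export
setGeneric("txSequence", function(object) standardGeneric("txSequence"))

setMethod("transcriptId", "TranscriptIsoform", function(object) object@transcriptId)
setMethod("geneSymbol", "TranscriptIsoform", function(object) object@gene)
setMethod("exons", "TranscriptIsoform", function(object) object@exons)
setMethod("cdsBounds", "TranscriptIsoform",
          function(object) c(start = object@cdsStart, end = object@cdsEnd))
setMethod("txSequence", "TranscriptIsoform", function(object) object@sequence)

#' @rdname GeneModel-class
#' @param object a \code{GeneModel}.
#' @export
setGeneric("isoforms", function(object) standardGeneric("isoforms"))
#' @rdname GeneModel-class
#' @export
setGeneric("geneLoci", function(object) standardGeneric("geneLoci"))
#' @rdname GeneModel-class
#' @export
setGeneric("proteinDomains", function(object, tx) standardGeneric("proteinDomains"))
#' @rdname GeneModel-class
#' @export
setGeneric("genomeBuild", function(object) standardGeneric("genomeBuild"))

setMethod("isoforms", "GeneModel", function(object) object@isoforms)
setMethod("geneLoci", "GeneModel", function(object) object@genes)
setMethod("proteinDomains", "GeneModel", function(object, tx) {
    if (missing(tx)) return(object@domains)
    object@domains[[tx]]
})
setMethod("genomeBuild", "GeneModel", function(object) object@build)

#' Retrieve one isoform from a GeneModel
#' @param object a \code{GeneModel}.
#' @param tx transcript id.
#' @return a \code{TranscriptIsoform}; error if absent.
#' @export
setGeneric("getIsoform", function(object, tx) standardGeneric("getIsoform"))
setMethod("getIsoform", "GeneModel", function(object, tx) {
    iso <- object@isoforms[[tx]]
    if (is.null(iso)) stop("unknown transcript id: ", tx)
    iso
})

#' Isoforms of one gene
#' @param object a \code{GeneModel}.
#' @param gene gene symbol.
#' @export
setGeneric("geneIsoforms", function(object, gene) standardGeneric("geneIsoforms"))
setMethod("geneIsoforms", "GeneModel", function(object, gene) {
    sel <- vapply(object@isoforms, function(i) i@gene == gene, logical(1))
    object@isoforms[sel]
})

#' @rdname FusionAnnotation-class
#' @param object a \code{FusionAnnotation}.
#' @export
setGeneric("annotationRecords", function(object) standardGeneric("annotationRecords"))
#' @rdname FusionAnnotation-class
#' @export
setGeneric("hasIsoformConflict", function(object) standardGeneric("hasIsoformConflict"))

setMethod("annotationRecords", "FusionAnnotation", function(object) object@records)
setMethod("hasIsoformConflict", "FusionAnnotation", function(object) object@conflict)

#' Evaluate an assay design against an event or junction
#'
#' Dispatches on the design class; see the class-specific behaviour in the
#' assay-evaluator documentation.
#'
#' @param design an \code{AssayDesign}.
#' @param event a \code{BreakpointEvent} or \code{FusionJunction}.
#' @param model a \code{GeneModel}.
#' @param ... evaluator-specific extras (e.g. \code{expression} counts for
#'   the imbalance assay).
#' @return an \code{AssayVerdict}.
#' @export
setGeneric("evaluateAssay",
           function(design, event, model, ...) standardGeneric("evaluateAssay"))

## ---- accessors for events ------------------------------------------------

#' @rdname ReadEvidence-class
#' @param object a \code{ReadEvidence}.
#' @export
setGeneric("readCounts", function(object) standardGeneric("readCounts"))
setMethod("readCounts", "ReadEvidence", function(object)
    c(split = object@splitReads, spanning = object@spanningPairs,
      wildtype = object@wildtypeReads))

#' @rdname AssayVerdict-class
#' @param object an \code{AssayVerdict}.
#' @export
setGeneric("isDetected", function(object) standardGeneric("isDetected"))
setMethod("isDetected", "AssayVerdict", function(object) object@detected)

#' @rdname AssayVerdict-class
#' @export
setGeneric("failureMode", function(object) standardGeneric("failureMode"))
setMethod("failureMode", "AssayVerdict", function(object) object@failureMode)

#' @rdname AssayVerdict-class
#' @export
setGeneric("partnerResolution", function(object) standardGeneric("partnerResolution"))
setMethod("partnerResolution", "AssayVerdict", function(object) object@partnerResolution)

#' @rdname ClinicalReport-class
#' @param object a \code{ClinicalReport}.
#' @export
setGeneric("reportFields", function(object) standardGeneric("reportFields"))
setMethod("reportFields", "ClinicalReport", function(object) object@fields)

#' @rdname ClinicalReport-class
#' @export
setGeneric("reportMarkdown", function(object) standardGeneric("reportMarkdown"))
setMethod("reportMarkdown", "ClinicalReport", function(object) object@markdown)

## ---- show methods --------------------------------------------------------

#' @rawNamespace exportMethods(show)
NULL

setMethod("show", "TranscriptIsoform", function(object) {
    cds <- if (is.na(object@cdsStart)) "non-coding"
           else sprintf("CDS %d-%d", object@cdsStart, object@cdsEnd)
    cat(sprintf("TranscriptIsoform %s (%s): %d exon(s), %s, %s strand\n",
                object@transcriptId, object@gene, length(object@exons), cds,
                as.character(strand(object@exons))[1]))
})

setMethod("show", "GeneModel", function(object) {
    cat(sprintf("GeneModel [%s]: %d gene(s), %d isoform(s)\n",
                object@build, length(object@genes), length(object@isoforms)))
    for (iso in object@isoforms)
        cat(sprintf("  %s (%s): %d exons\n", iso@transcriptId, iso@gene,
                    length(iso@exons)))
})

setMethod("show", "BreakpointEvent", function(object) {
    p <- if (is.null(object@breakend3)) object@partnerStatus
         else sprintf("%s:%d", object@breakend3@chrom, object@breakend3@pos)
    br <- if (!is.na(object@insertSeq)) sprintf(" [bridged, %dnt insert]",
                                                nchar(object@insertSeq)) else ""
    cat(sprintf("BreakpointEvent %s: %s:%d -> %s%s\n", object@id,
                object@breakend5@chrom, object@breakend5@pos, p, br))
})

setMethod("show", "FusionJunction", function(object) {
    cat(sprintf("FusionJunction %s: %s/%s exon %s(+%d) :: %s/%s exon %s(+%d)\n",
                object@id, object@gene5, object@tx5, object@exon5, object@offset5,
                object@gene3, object@tx3, object@exon3, object@offset3))
})

setMethod("show", "FusionAnnotation", function(object) {
    cat(sprintf("FusionAnnotation %s: %d isoform record(s)%s\n", object@eventId,
                nrow(object@records),
                if (isTRUE(object@conflict)) " [isoform conflict]" else ""))
})

setMethod("show", "AssayVerdict", function(object) {
    cat(sprintf("AssayVerdict [%s] %s: %s (partner: %s, failure: %s)\n",
                object@assay, object@eventId,
                if (object@detected) "DETECTED" else "not detected",
                object@partnerResolution, object@failureMode))
})

setMethod("show", "ClinicalReport", function(object) {
    cat(sprintf("ClinicalReport (%s level), %d field(s)\n",
                object@level, length(object@fields)))
})
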