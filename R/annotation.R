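## Interpretive core: breakpoint localization, reading frame, kinase-domain
## retention, oncogenic mechanism, per-isoform conflict surfacing.

#' Localize a breakend on one isoform
#'
#' Region assignment is deterministic; a position exactly at an exon/intron
#' boundary belongs to the intron (the junction sits after the exon), so a
#' break "after exon 17" localizes to intron 17.
#'
#' @param bp a \code{Breakend}.
#' @param iso a \code{TranscriptIsoform}.
#' @return one-row data.frame: \code{region} (one of \code{"exon (CDS)"},
#'   \code{"exon (UTR)"}, \code{"intron"}, \code{"upstream"},
#'   \code{"downstream"}), \code{index}, \code{label}, \code{cdna}.
#' @export
localizeBreakend <- function(bp, iso) {
    m <- genomicToTranscript(iso, bp@pos, chrom = bp@chrom)
    region <- m$region
    if (region == "exon") {
        cds <- !is.na(iso@cdsStart) &&
            m$cdna >= iso@cdsStart && m$cdna <= iso@cdsEnd
        region <- if (cds) "exon (CDS)" else "exon (UTR)"
    }
    data.frame(region = region, index = m$index, label = m$label,
               cdna = m$cdna, stringsAsFactors = FALSE)
}

# cDNA length of the transcript prefix retained by a driver-side break
.retainedPrefix <- function(iso, loc) {
    w <- width(iso@exons)
    switch(sub(" .*", "", loc$region),
        exon = loc$cdna,
        intron = sum(w[seq_len(loc$index)]),
        upstream = 0L,
        downstream = sum(w))
}

# retained CDS nucleotides given a retained cDNA prefix
.retainedCds <- function(iso, prefix) {
    if (is.na(iso@cdsStart)) return(0L)
    max(0L, min(prefix, iso@cdsEnd) - iso@cdsStart + 1L)
}

#' Is the kinase domain retained 5' of a driver-side break?
#'
#' Two rules are evaluated. The positional rule: only rearrangements
#' involving exon 17, intron 17 or the protein-coding region of the exon
#' after 17 keep the kinase domain (anything upstream of exon 17 loses it).
#' The general amino-acid rule: the retained cDNA prefix translates the full
#' kinase domain. The two agree everywhere except for breaks inside exon 17
#' upstream of the kinase C-terminal codon, which are flagged with a
#' discrepancy warning rather than silently resolved.
#'
#' @param loc localization of the driver-side break (from
#'   \code{localizeBreakend}).
#' @param iso driver \code{TranscriptIsoform}.
#' @param domains domain table of \code{iso} (with a \code{kinase} row).
#' @return list with \code{retained} (logical, the amino-acid rule) and
#'   \code{warning} (TRUE when the two rules disagree).
#' @export
kinaseRetained <- function(loc, iso, domains) {
    kin <- domains[domains$name == "kinase", ]
    if (nrow(kin) == 0L) return(list(retained = FALSE, warning = FALSE))
    prefix <- .retainedPrefix(iso, loc)
    aa <- .retainedCds(iso, prefix) %/% 3L
    aaRule <- aa >= kin$aa_end[1]

    labels <- mcols(iso@exons)$exon_label
    r17 <- match("17", labels)
    after17 <- if (!is.na(r17) && r17 < length(labels)) labels[r17 + 1L]
               else NA_character_
    exonRule <- (loc$region == "intron" && identical(loc$label, "17")) ||
        (loc$region == "exon (CDS)" &&
         (identical(loc$label, "17") || identical(loc$label, after17)))
    list(retained = aaRule, warning = !identical(aaRule, exonRule))
}

## ---- reading frame -------------------------------------------------------

.STOP_CODONS <- c("TAA", "TAG", "TGA")

# Frame verdict for one driver-isoform/partner-isoform pair.
# l5: retained driver CDS nt; iso3/p3: partner isoform and the cDNA position
# of its first retained base. Codon phase is preserved iff l5 = q (mod 3)
# where q is the number of partner CDS nt lost 5' of the junction; a junction
# that splits a codon can create a hybrid stop, checked when sequences exist.
.framePair <- function(iso5, l5, iso3, p3) {
    if (is.null(iso3) || is.na(p3)) return(list(frame = "indeterminate", q = NA))
    if (is.na(iso3@cdsStart)) return(list(frame = "no_cds_3p", q = NA))
    q <- p3 - iso3@cdsStart
    if (q < 0L) return(list(frame = "no_cds_3p", q = q))
    if (p3 > iso3@cdsEnd - 3L) return(list(frame = "no_cds_3p", q = q))
    if ((l5 %% 3L) != (q %% 3L)) return(list(frame = "out_of_frame", q = q))
    phase <- l5 %% 3L
    if (phase != 0L && !is.null(iso5@sequence) && !is.null(iso3@sequence)) {
        tail5 <- as.character(subseq(iso5@sequence,
            iso5@cdsStart + l5 - phase, iso5@cdsStart + l5 - 1L))
        head3 <- as.character(subseq(iso3@sequence, p3, p3 + (3L - phase) - 1L))
        if (paste0(tail5, head3) %in% .STOP_CODONS)
            return(list(frame = "out_of_frame", q = q))
    }
    list(frame = "in_frame", q = q)
}

# first partner amino acid fully encoded 3' of the junction
.firstRetainedAa <- function(q) {
    if (is.na(q) || q < 0L) return(NA_integer_)
    if (q %% 3L == 0L) q %/% 3L + 1L else q %/% 3L + 2L
}

# cDNA position of the first retained partner base for a junction side
.partnerEntry <- function(iso3, exon3, offset3) {
    labels <- mcols(iso3@exons)$exon_label
    r <- match(as.character(exon3), labels)
    if (is.na(r)) return(NA_integer_)
    w <- width(iso3@exons)
    p3 <- (if (r > 1L) sum(w[seq_len(r - 1L)]) else 0L) + 1L + offset3
    if (p3 > sum(w)) return(NA_integer_)
    p3
}

# retained driver CDS nt for a junction side (exon label + trim offset)
.driverRetained <- function(iso5, exon5, offset5) {
    labels <- mcols(iso5@exons)$exon_label
    r <- match(as.character(exon5), labels)
    if (is.na(r)) return(NA_integer_)
    prefix <- sum(width(iso5@exons)[seq_len(r)]) - offset5
    .retainedCds(iso5, prefix)
}

#' Reading-frame status of an RNA fusion junction, per partner isoform
#'
#' A junction is in frame when the codon phase of the retained driver CDS
#' matches the phase of the partner CDS at the junction (and no hybrid stop
#' codon is created); it is \code{no_cds_3p} when the junction lies upstream
#' of the partner isoform's start codon; partner isoforms that do not carry
#' the junction exon are \code{indeterminate}, not an error.
#'
#' @param j a \code{FusionJunction}.
#' @param model a \code{GeneModel} containing the driver gene.
#' @return data.frame with one row per partner isoform: \code{isoform3},
#'   \code{frame}, \code{q} (partner CDS nt lost 5' of the junction).
#' @export
frameStatus <- function(j, model) {
    iso5 <- if (j@tx5 %in% names(model@isoforms)) getIsoform(model, j@tx5)
            else canonicalIsoform(model, j@gene5)
    l5 <- .driverRetained(iso5, j@exon5, j@offset5)
    partners <- geneIsoforms(model, j@gene3)
    if (length(partners) == 0L)
        return(data.frame(isoform3 = j@tx3, frame = "indeterminate", q = NA,
                          stringsAsFactors = FALSE))
    do.call(rbind, lapply(partners, function(iso3) {
        p3 <- .partnerEntry(iso3, j@exon3, j@offset3)
        fr <- if (is.na(l5)) list(frame = "indeterminate", q = NA)
              else .framePair(iso5, l5, iso3, p3)
        data.frame(isoform3 = iso3@transcriptId, frame = fr$frame,
                   q = if (is.null(fr$q)) NA else fr$q,
                   stringsAsFactors = FALSE)
    }))
}

## ---- mechanism -----------------------------------------------------------

#' Classify the oncogenic mechanism of one isoform-pair record
#'
#' Without a retained kinase domain there is no mechanism. With it, an
#' in-frame fusion gaining a flagged dimerisation/oligomerisation domain acts
#' through enhanced dimerisation; loss of the C-terminal YLDL motif acts
#' through C-terminal truncation regardless of frame or partner content; a
#' DNA-only event whose partner sequence content is unknown (bridged,
#' unresolved) is indeterminate unless truncation is forced by having no
#' partner at all.
#'
#' @param kinaseRet logical, kinase retained.
#' @param frame frame value.
#' @param yldlLost logical, YLDL motif lost from the retained driver portion.
#' @param partnerPresent logical, any partner sequence joined.
#' @param partnerKnown logical, partner sequence content resolved.
#' @param dimerRetained logical, a flagged dimerisation domain fully retained.
#' @return one of \code{"enhanced_dimerisation"},
#'   \code{"c_terminal_truncation"}, \code{"none"}, \code{"indeterminate"}.
#' @export
classifyMechanism <- function(kinaseRet, frame, yldlLost, partnerPresent,
                              partnerKnown, dimerRetained) {
    if (!isTRUE(kinaseRet)) return("none")
    if (!partnerPresent)
        return(if (yldlLost) "c_terminal_truncation" else "none")
    if (!partnerKnown) return("indeterminate")
    if (identical(frame, "in_frame") && isTRUE(dimerRetained))
        return("enhanced_dimerisation")
    if (yldlLost &&
        (frame %in% c("out_of_frame", "no_cds_3p") || !isTRUE(dimerRetained)))
        return("c_terminal_truncation")
    if (identical(frame, "indeterminate")) return("indeterminate")
    "none"
}

# dimerisation domains of iso3 fully retained 3' of the junction
.dimerRetained <- function(model, iso3, q) {
    d <- model@domains[[iso3@transcriptId]]
    if (is.null(d) || nrow(d) == 0L) return(list(any = FALSE, names = character()))
    firstAa <- .firstRetainedAa(q)
    if (is.na(firstAa)) return(list(any = FALSE, names = character()))
    keep <- d[d$dimerisation & d$aa_start >= firstAa, , drop = FALSE]
    list(any = nrow(keep) > 0L, names = keep$name)
}

## ---- event annotation ----------------------------------------------------

.geneAt <- function(model, chrom, pos) {
    g <- model@genes
    hit <- which(as.character(seqnames(g)) == chrom & start(g) <= pos &
                 end(g) >= pos)
    if (length(hit) == 0L) NA_character_ else names(g)[hit[1]]
}

.regionString <- function(loc) {
    switch(sub(" .*", "", loc$region),
        exon = sprintf("%s %s", loc$region, loc$label),
        intron = sprintf("intron %s", loc$label),
        loc$region)
}

# one annotation row
.annRow <- function(iso5, iso3id, region5, region3, cdna5, frame, kin, mech,
                    lost, grb2, partnerDoms) {
    data.frame(isoform5 = iso5, isoform3 = iso3id, region5 = region5,
               region3 = region3, cdna5 = cdna5, frame = frame,
               kinase_retained = kin$retained, kinase_warning = kin$warning,
               mechanism = mech,
               competent = kin$retained && mech != "none",
               lost_motifs = paste(lost, collapse = ","),
               grb2_site_lost = grb2,
               retained_partner_domains = paste(partnerDoms, collapse = ","),
               stringsAsFactors = FALSE)
}

.driverFlags <- function(iso5, domains5, l5) {
    aa <- l5 %/% 3L
    yldl <- domains5[domains5$name == "YLDL", ]
    yldlLost <- if (nrow(yldl)) aa < yldl$aa_end[1] else TRUE
    protLen <- if (is.na(iso5@cdsStart)) 0L
               else (iso5@cdsEnd - iso5@cdsStart + 1L) %/% 3L - 1L
    list(aa = aa, yldlLost = yldlLost,
         lost = if (yldlLost && nrow(yldl)) "YLDL" else character(),
         grb2 = aa < protLen - 9L)
}

#' Annotate a fusion event across all isoform pairs
#'
#' Produces one record per driver-isoform x partner-isoform pair with
#' localization, frame, kinase retention, mechanism and competence
#' (competent = kinase retained and mechanism not none). A conflict flag is
#' set when isoforms disagree on frame or mechanism — the situation in which
#' a breakpoint is 5' UTR on one partner isoform but intron 1 (in-frame) on
#' another, so no single collapsed verdict exists.
#'
#' @param event a \code{BreakpointEvent} or \code{FusionJunction}.
#' @param model a \code{GeneModel} containing the driver gene.
#' @param catalog optional partner domain catalog (defaults to the model's).
#' @return a \code{FusionAnnotation}.
#' @export
annotateEvent <- function(event, model, catalog = NULL) {
    if (is(event, "FusionJunction")) .annotateJunction(event, model)
    else if (is(event, "BreakpointEvent")) .annotateBreakpoint(event, model)
    else stop("event must be a BreakpointEvent or FusionJunction")
}

.annotateJunction <- function(j, model) {
    driverIsos <- geneIsoforms(model, j@gene5)
    if (length(driverIsos) == 0L)
        stop("driver gene ", j@gene5, " absent from gene model")
    partners <- geneIsoforms(model, j@gene3)
    rows <- list()
    for (iso5 in driverIsos) {
        dom5 <- model@domains[[iso5@transcriptId]]
        l5 <- .driverRetained(iso5, j@exon5, j@offset5)
        if (is.na(l5)) {
            rows[[length(rows) + 1L]] <- .annRow(iso5@transcriptId,
                if (length(partners)) vapply(partners, slot, "", "transcriptId")[1]
                else j@tx3,
                "not_on_isoform", NA_character_, NA_integer_, "indeterminate",
                list(retained = FALSE, warning = FALSE), "indeterminate",
                character(), FALSE, character())
            next
        }
        labels <- mcols(iso5@exons)$exon_label
        r5 <- match(as.character(j@exon5), labels)
        loc5 <- if (j@offset5 == 0L)
            data.frame(region = "intron", index = r5, label = labels[r5],
                       cdna = NA_integer_)
        else
            data.frame(region = "exon (CDS)", index = r5, label = labels[r5],
                       cdna = sum(width(iso5@exons)[seq_len(r5)]) - j@offset5)
        kin <- kinaseRetained(loc5, iso5, dom5)
        fl <- .driverFlags(iso5, dom5, l5)
        if (length(partners) == 0L) {
            mech <- classifyMechanism(kin$retained, "indeterminate",
                                      fl$yldlLost, TRUE, FALSE, FALSE)
            rows[[length(rows) + 1L]] <- .annRow(iso5@transcriptId, j@tx3,
                .regionString(loc5), sprintf("exon %s (novel partner)", j@exon3),
                loc5$cdna, "indeterminate", kin, mech, fl$lost, fl$grb2,
                character())
            next
        }
        for (iso3 in partners) {
            p3 <- .partnerEntry(iso3, j@exon3, j@offset3)
            fr <- if (is.na(p3)) list(frame = "indeterminate", q = NA_integer_)
                  else .framePair(iso5, l5, iso3, p3)
            dim3 <- .dimerRetained(model, iso3, fr$q)
            mech <- classifyMechanism(kin$retained, fr$frame, fl$yldlLost,
                                      TRUE, TRUE, dim3$any)
            rows[[length(rows) + 1L]] <- .annRow(iso5@transcriptId,
                iso3@transcriptId, .regionString(loc5),
                sprintf("exon %s", j@exon3), loc5$cdna, fr$frame, kin, mech,
                fl$lost, fl$grb2, if (mech == "enhanced_dimerisation")
                    dim3$names else character())
        }
    }
    .finishAnnotation(j@id, rows)
}

.annotateBreakpoint <- function(ev, model) {
    driverGene <- .geneAt(model, ev@breakend5@chrom, ev@breakend5@pos)
    if (is.na(driverGene))
        stop("driver breakend of ", ev@id, " lies in no modeled gene")
    driverIsos <- geneIsoforms(model, driverGene)
    bridged <- !is.na(ev@insertSeq) || identical(ev@partnerStatus, "ambiguous")
    partnerGene <- if (!is.null(ev@breakend3))
        .geneAt(model, ev@breakend3@chrom, ev@breakend3@pos) else NA_character_
    deletion <- identical(partnerGene, driverGene)
    partnerless <- is.null(ev@breakend3) || is.na(partnerGene) || deletion
    partners <- if (!partnerless && !bridged) geneIsoforms(model, partnerGene)
                else list()

    rows <- list()
    for (iso5 in driverIsos) {
        dom5 <- model@domains[[iso5@transcriptId]]
        loc5 <- localizeBreakend(ev@breakend5, iso5)
        kin <- kinaseRetained(loc5, iso5, dom5)
        l5 <- .retainedCds(iso5, .retainedPrefix(iso5, loc5))
        fl <- .driverFlags(iso5, dom5, l5)
        if (length(partners) == 0L) {
            mech <- classifyMechanism(kin$retained, "indeterminate",
                fl$yldlLost, partnerPresent = bridged && !partnerless,
                partnerKnown = FALSE, dimerRetained = FALSE)
            region3 <- if (deletion) "intragenic 3' deletion"
                       else if (bridged) "bridged insert (unresolved)"
                       else "intergenic/unmapped"
            rows[[length(rows) + 1L]] <- .annRow(iso5@transcriptId,
                NA_character_, .regionString(loc5), region3, loc5$cdna,
                "indeterminate", kin, mech, fl$lost, fl$grb2, character())
            next
        }
        for (iso3 in partners) {
            loc3 <- localizeBreakend(ev@breakend3, iso3)
            # implied spliced entry point on the partner transcript
            p3 <- switch(sub(" .*", "", loc3$region),
                exon = loc3$cdna,
                intron = {  # splice joins the next exon in transcript order
                    w <- width(iso3@exons)
                    if (loc3$index < length(w))
                        sum(w[seq_len(loc3$index)]) + 1L else NA_integer_
                },
                upstream = 1L,
                downstream = NA_integer_)
            fr <- .framePair(iso5, l5, iso3, p3)
            dim3 <- .dimerRetained(model, iso3, fr$q)
            mech <- classifyMechanism(kin$retained, fr$frame, fl$yldlLost,
                                      TRUE, TRUE, dim3$any)
            rows[[length(rows) + 1L]] <- .annRow(iso5@transcriptId,
                iso3@transcriptId, .regionString(loc5), .regionString(loc3),
                loc5$cdna, fr$frame, kin, mech, fl$lost, fl$grb2,
                if (mech == "enhanced_dimerisation") dim3$names else character())
        }
    }
    .finishAnnotation(ev@id, rows)
}

.finishAnnotation <- function(id, rows) {
    rec <- do.call(rbind, rows)
    informative <- rec[rec$frame != "indeterminate", , drop = FALSE]
    conflict <- nrow(informative) > 1L &&
        (length(unique(informative$frame)) > 1L ||
         length(unique(informative$mechanism)) > 1L)
    new("FusionAnnotation", eventId = id, records = rec, conflict = conflict)
}

#' Annotate a list of events
#' @param events list of \code{BreakpointEvent}/\code{FusionJunction}.
#' @param model a \code{GeneModel}.
#' @return list of \code{FusionAnnotation}.
#' @export
annotateCohort <- function(events, model)
    lapply(events, annotateEvent, model = model)

#' Flatten annotations to one table
#'
#' @param annList list of \code{FusionAnnotation}.
#' @return data.frame, one row per event x isoform pair, with \code{event_id}
#'   and \code{isoform_conflict} columns prepended.
#' @export
annotationTable <- function(annList) {
    do.call(rbind, lapply(annList, function(a) {
        cbind(data.frame(event_id = a@eventId,
                         isoform_conflict = a@conflict,
                         stringsAsFactors = FALSE),
              a@records)
    }))
}
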