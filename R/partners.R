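## Toy partner-gene models. The genes are modeled on recurrent FGFR2 fusion
## partners in iCCA (symbols real, coordinates synthetic): ATE1 and TACC2 sit
## within interphase-FISH resolution of the FGFR2 locus, BICC1/CCDC6/WAC are
## distant partners on chr10, KCTD1 carries isoform-dependent start codons,
## DBP is the bridged-fusion target, AFF3 contributes its eponymous
## oligomerisation domain. Dimerisation-competent domains are flagged.

# One toy isoform: exon 1 holds the 5' UTR, the last exon the 3' UTR; CDS
# nucleotide widths per exon are given directly. utr5Exon1 = extra UTR exon
# before the CDS-bearing exons (KCTD1 canonical pattern) is handled by
# cdsWidths[1] == 0.
.toyIsoform <- function(txId, gene, chrom, strand, txStart, utr5, cdsWidths,
                        utr3, intron = 2000L, labels = NULL, protein = NULL) {
    n <- length(cdsWidths)
    widths <- cdsWidths
    widths[1] <- widths[1] + utr5
    widths[n] <- widths[n] + utr3
    starts <- integer(n)
    starts[1] <- txStart
    for (k in seq_len(n - 1L))
        starts[k + 1L] <- starts[k] + widths[k] + intron
    cdsLen <- sum(cdsWidths)
    stopifnot(cdsLen %% 3L == 0L)
    nAA <- cdsLen %/% 3L - 1L
    if (is.null(protein)) {
        aa <- .aaCycle(nAA); aa[1] <- "M"
        protein <- paste0(aa, collapse = "")
    }
    cds <- .backTranslate(paste0(protein, "*"))
    sequence <- paste0(.utrSeq(utr5), cds, .utrSeq(utr3))
    transcriptIsoform(txId, gene, chrom, strand,
        exonStarts = starts, exonWidths = widths, labels = labels,
        cdsStart = utr5 + 1L, cdsEnd = utr5 + cdsLen, sequence = sequence)
}

.dom <- function(name, from, to, dimer = FALSE)
    data.frame(name = name, aa_start = as.integer(from), aa_end = as.integer(to),
               dimerisation = dimer, stringsAsFactors = FALSE)

#' Synthetic models of recurrent FGFR2 partner genes
#'
#' @return a \code{GeneModel} holding the eight toy partner genes (no driver).
#' @export
partnerGeneModel <- function() {
    isoforms <- list()
    domains <- list()
    lociL <- list()

    addGene <- function(sym, isoL, domL = NULL, pad = 5000L) {
        for (iso in isoL) isoforms[[iso@transcriptId]] <<- iso
        ex <- unlist(lapply(isoL, function(i) c(min(start(i@exons)),
                                                max(end(i@exons)))))
        g <- GRanges(as.character(seqnames(isoL[[1]]@exons))[1],
                     IRanges(min(ex) - pad, max(ex) + pad),
                     strand = as.character(strand(isoL[[1]]@exons))[1])
        names(g) <- sym
        lociL[[sym]] <<- g
        if (!is.null(domL))
            for (tx in names(domL)) domains[[tx]] <<- domL[[tx]]
    }

    # ATE1: close-proximity partner, ~140 kb from the FGFR2 locus, 13 exons,
    # no dimerisation domain (in-frame fusions act through FGFR2 truncation)
    ate1 <- .toyIsoform("NM_007041.3", "ATE1", "chr10", "+", 123500000L,
        utr5 = 60L, cdsWidths = c(90L, rep(120L, 11L), 90L), utr3 = 200L)
    addGene("ATE1", list(ate1),
            list("NM_007041.3" = .dom("arginyltransferase core", 50L, 400L)))

    # TACC2: second close-proximity partner, coiled-coil C-terminus
    tacc2 <- .toyIsoform("NM_006997.4", "TACC2", "chr10", "+", 123900000L,
        utr5 = 80L, cdsWidths = c(120L, rep(150L, 8L), 120L), utr3 = 250L)
    addGene("TACC2", list(tacc2),
            list("NM_006997.4" = .dom("coiled-coil", 300L, 450L, TRUE)))

    # BICC1: the archetypal distant partner, SAM oligomerisation domain
    bicc1 <- .toyIsoform("NM_001080512.3", "BICC1", "chr10", "+", 60200000L,
        utr5 = 120L, cdsWidths = c(150L, rep(180L, 8L), 120L), utr3 = 300L)
    addGene("BICC1", list(bicc1),
            list("NM_001080512.3" = rbind(.dom("KH", 40L, 160L),
                                          .dom("SAM", 450L, 520L, TRUE))))

    # CCDC6: distant partner with an N-proximal coiled-coil; the amplicon
    # worked example queries junctions on its exons 1-4
    ccdc6 <- .toyIsoform("NM_005436.5", "CCDC6", "chr10", "+", 61500000L,
        utr5 = 100L, cdsWidths = c(153L, 120L, 150L, 120L, 135L, 120L),
        utr3 = 220L)
    addGene("CCDC6", list(ccdc6),
            list("NM_005436.5" = .dom("coiled-coil", 60L, 150L, TRUE)))

    # KCTD1: three isoforms with different transcription/translation starts.
    # The canonical isoform begins with a long non-coding first exon; the two
    # alternatives use a short coding first exon, so a genomic position can
    # be 5' UTR on the canonical isoform yet intron 1 on the alternatives.
    kShared <- function(txId, utr3) .toyIsoform(txId, "KCTD1", "chr18", "+",
        24000000L, utr5 = 100L, cdsWidths = c(300L, 241L, 150L, 140L),
        utr3 = utr3, intron = 4600L)
    kctd1canon <- transcriptIsoform("NM_001142730.3", "KCTD1", "chr18", "+",
        exonStarts = c(24000000L, 24005000L, 24009841L, 24014591L),
        exonWidths = c(2000L, 241L, 150L, 290L),
        cdsStart = 2000L + 40L + 1L, cdsEnd = 2000L + 40L + 441L,
        sequence = {
            aa <- .aaCycle(146L); aa[1] <- "M"
            paste0(.utrSeq(2040L), .backTranslate(paste0(paste0(aa, collapse = ""),
                   "*")), .utrSeq(200L))
        })
    kctd1alt1 <- kShared("NM_001258222.3", utr3 = 150L)
    kctd1alt2 <- kShared("NM_198991.3", utr3 = 300L)
    addGene("KCTD1", list(kctd1canon, kctd1alt1, kctd1alt2), {
        btb <- .dom("BTB/POZ", 120L, 220L, TRUE)
        list("NM_001142730.3" = .dom("BTB/POZ", 30L, 130L, TRUE),
             "NM_001258222.3" = btb, "NM_198991.3" = btb)
    })

    # DBP: bridged-fusion target on chr19, leucine zipper
    dbp <- .toyIsoform("NM_001352.4", "DBP", "chr19", "+", 49100000L,
        utr5 = 80L, cdsWidths = c(150L, 150L, 150L, 180L, 159L), utr3 = 120L)
    addGene("DBP", list(dbp),
            list("NM_001352.4" = rbind(.dom("PAR bZIP", 120L, 200L),
                                       .dom("leucine zipper", 220L, 260L, TRUE))))

    # AFF3: contributes the AFF oligomerisation domain
    aff3 <- .toyIsoform("NM_002285.3", "AFF3", "chr2", "+", 100000000L,
        utr5 = 200L, cdsWidths = c(120L, rep(180L, 10L), 120L), utr3 = 300L)
    addGene("AFF3", list(aff3),
            list("NM_002285.3" = .dom("AFF3", 400L, 600L, TRUE)))

    # WAC: distant chr10 partner with coiled-coil
    wac <- .toyIsoform("NM_016628.5", "WAC", "chr10", "+", 28800000L,
        utr5 = 90L, cdsWidths = c(120L, rep(150L, 6L), 120L), utr3 = 200L)
    addGene("WAC", list(wac),
            list("NM_016628.5" = .dom("coiled-coil", 100L, 200L, TRUE)))

    genes <- suppressWarnings(do.call(c, unname(lociL)))
    m <- new("GeneModel", genes = genes, isoforms = isoforms,
             domains = domains, build = "hg19")
    validObject(m)
    m
}

#' The working model: FGFR2 fixture plus toy partner genes
#'
#' @return a \code{GeneModel} combining \code{fgfr2GeneModel()} and
#'   \code{partnerGeneModel()}.
#' @export
fusionGeneModel <- function() {
    f <- fgfr2GeneModel()
    p <- partnerGeneModel()
    m <- new("GeneModel",
             genes = suppressWarnings(c(f@genes, p@genes)),
             isoforms = c(f@isoforms, p@isoforms),
             domains = c(f@domains, p@domains),
             build = "hg19", altRegions = f@altRegions)
    validObject(m)
    m
}

#' Canonical isoform per gene
#'
#' The first bundled isoform of each gene is treated as canonical
#' (NM_000141.4 for FGFR2, NM_001142730.3 for KCTD1).
#'
#' @param model a \code{GeneModel}.
#' @param gene gene symbol.
#' @return a \code{TranscriptIsoform}.
#' @export
canonicalIsoform <- function(model, gene) {
    isoL <- geneIsoforms(model, gene)
    if (length(isoL) == 0L) stop("gene not in model: ", gene)
    isoL[[1]]
}

#' Partner dimerisation-domain catalog
#'
#' Maps each gene to its protein domains with a dimerisation flag. Flagged
#' domain families follow the published list of strong dimerisation or
#' oligomerisation modules (AFF3, BAG, BAR, coiled-coil, FN1, leucine
#' zipper, LIS1, SAM, SPHF, zinc finger); domains outside that list may be
#' flagged explicitly (the KCTD1 BTB/POZ oligomerisation module is).
#'
#' @param model a \code{GeneModel}.
#' @return named list: gene symbol -> data.frame of domains (on the gene's
#'   canonical isoform) with a \code{dimerisation} column.
#' @export
partnerDomainCatalog <- function(model) {
    out <- list()
    for (g in names(model@genes)) {
        iso <- canonicalIsoform(model, g)
        d <- model@domains[[iso@transcriptId]]
        if (!is.null(d)) out[[g]] <- d
    }
    out
}

#' Domain families treated as dimerisation/oligomerisation-competent
#' @export
dimerisationDomainTypes <- c("AFF3", "BAG", "BAR", "coiled-coil", "FN1",
                             "leucine zipper", "LIS1", "SAM", "SPHF",
                             "zinc finger")
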