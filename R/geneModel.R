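#' @importFrom Biostrings DNAString AAString GENETIC_CODE translate
#'   matchPattern subseq reverseComplement
#' @importFrom IRanges start end width
NULL

## Deterministic one-codon-per-amino-acid back-translation table (first codon
## in alphabetical order for each residue; stop codon TAA).
.codonFor <- local({
    codons <- sort(names(Biostrings::GENETIC_CODE))
    aa <- Biostrings::GENETIC_CODE[codons]
    tab <- tapply(codons, aa, function(x) x[[1]])
    tab[["*"]] <- "TAA"
    tab
})

.backTranslate <- function(aaString) {
    paste0(.codonFor[strsplit(aaString, "")[[1]]], collapse = "")
}

#' Low-level TranscriptIsoform constructor
#'
#' @param transcriptId,gene identifiers.
#' @param chrom chromosome; \code{strand} "+" or "-".
#' @param exonStarts,exonWidths genomic starts (1-based) and widths, given in
#'   transcript order (genomic starts decrease along the vector for "-").
#' @param labels display exon labels (default: ranks as character).
#' @param cdsStart,cdsEnd 1-based cDNA CDS bounds (stop codon included).
#' @param sequence spliced transcript sequence (character or DNAString), optional.
#' @return a validated \code{TranscriptIsoform}.
#' @export
transcriptIsoform <- function(transcriptId, gene, chrom, strand,
                              exonStarts, exonWidths, labels = NULL,
                              cdsStart = NA, cdsEnd = NA, sequence = NULL) {
    n <- length(exonStarts)
    stopifnot(length(exonWidths) == n)
    if (is.null(labels)) labels <- as.character(seq_len(n))
    gr <- GRanges(chrom, IRanges(start = exonStarts, width = exonWidths),
                  strand = strand)
    mcols(gr)$exon_label <- as.character(labels)
    mcols(gr)$exon_rank <- seq_len(n)
    if (is.character(sequence)) sequence <- DNAString(sequence)
    new("TranscriptIsoform", transcriptId = transcriptId, gene = gene,
        exons = gr, cdsStart = as.integer(cdsStart), cdsEnd = as.integer(cdsEnd),
        sequence = sequence)
}

#' Protein length of a coding isoform
#'
#' Stop codon excluded: an isoform whose CDS (including the stop) is 2466 nt
#' encodes 821 amino acids.
#'
#' @param iso a \code{TranscriptIsoform}.
#' @return amino-acid count.
#' @export
proteinLength <- function(iso) {
    stopifnot(is(iso, "TranscriptIsoform"))
    if (is.na(iso@cdsStart))
        stop("isoform ", iso@transcriptId, " is non-coding: no CDS")
    (iso@cdsEnd - iso@cdsStart + 1L) %/% 3L - 1L
}

#' Translated protein of a coding isoform (stop removed)
#'
#' @param iso a \code{TranscriptIsoform} with sequence and CDS.
#' @return an \code{AAString}.
#' @export
isoformProtein <- function(iso) {
    if (is.null(iso@sequence)) stop("isoform has no sequence")
    if (is.na(iso@cdsStart)) stop("isoform is non-coding: no CDS")
    cds <- subseq(iso@sequence, iso@cdsStart, iso@cdsEnd)
    aa <- Biostrings::translate(cds)
    subseq(aa, 1L, length(aa) - 1L)
}

#' Map genomic positions onto transcript (cDNA) coordinates
#'
#' Exonic positions get a 1-based cDNA coordinate respecting strand; intronic
#' positions get an intron descriptor (intron index k = the intron after the
#' k-th exon in transcript order, plus the distance to the nearest splice
#' site); positions beyond the transcript span are flagged upstream or
#' downstream (in transcript orientation).
#'
#' @param iso a \code{TranscriptIsoform}.
#' @param pos vector of 1-based genomic positions on the isoform's chromosome.
#' @param chrom optional chromosome of \code{pos}; error when it differs from
#'   the isoform's.
#' @return data.frame with columns \code{genomic}, \code{region} (one of
#'   \code{exon}, \code{intron}, \code{upstream}, \code{downstream}),
#'   \code{index} (exon rank or intron index), \code{label}, \code{cdna},
#'   \code{splice_dist}.
#' @export
genomicToTranscript <- function(iso, pos, chrom = NULL) {
    ex <- iso@exons
    isoChrom <- as.character(seqnames(ex))[1]
    if (!is.null(chrom) && any(chrom != isoChrom))
        stop("position(s) on chromosome ", paste(unique(chrom), collapse = ","),
             " but isoform ", iso@transcriptId, " is on ", isoChrom)
    minus <- as.character(strand(ex))[1] == "-"
    s <- start(ex); e <- end(ex); w <- width(ex)
    cum <- c(0L, cumsum(w))[seq_along(w)]  # cDNA bases before each exon
    n <- length(pos)
    region <- character(n); index <- rep(NA_integer_, n)
    label <- rep(NA_character_, n); cdna <- rep(NA_integer_, n)
    sdist <- rep(NA_integer_, n)
    labels <- mcols(ex)$exon_label
    for (i in seq_len(n)) {
        p <- pos[i]
        hit <- which(p >= s & p <= e)
        if (length(hit) == 1L) {
            region[i] <- "exon"; index[i] <- hit; label[i] <- labels[hit]
            cdna[i] <- cum[hit] + if (minus) e[hit] - p + 1L else p - s[hit] + 1L
            next
        }
        # transcript-orientation flanks
        if (minus) {
            if (p > e[1]) { region[i] <- "upstream"; next }
            if (p < s[length(s)]) { region[i] <- "downstream"; next }
        } else {
            if (p < s[1]) { region[i] <- "upstream"; next }
            if (p > e[length(e)]) { region[i] <- "downstream"; next }
        }
        # intron k lies between exon k and exon k+1 in transcript order
        for (k in seq_len(length(s) - 1L)) {
            lo <- if (minus) e[k + 1L] + 1L else e[k] + 1L
            hi <- if (minus) s[k] - 1L else s[k + 1L] - 1L
            if (p >= lo && p <= hi) {
                region[i] <- "intron"; index[i] <- k
                label[i] <- labels[k]
                sdist[i] <- min(p - lo + 1L, hi - p + 1L)
                break
            }
        }
        if (region[i] == "") region[i] <- "intron"  # unreachable guard
    }
    data.frame(genomic = pos, region = region, index = index, label = label,
               cdna = cdna, splice_dist = sdist, stringsAsFactors = FALSE)
}

#' Inverse mapping: cDNA coordinate to genomic position
#'
#' @param iso a \code{TranscriptIsoform}.
#' @param cdna vector of 1-based cDNA positions.
#' @return integer vector of genomic positions.
#' @export
transcriptToGenomic <- function(iso, cdna) {
    ex <- iso@exons
    minus <- as.character(strand(ex))[1] == "-"
    s <- start(ex); e <- end(ex); w <- width(ex)
    cum <- c(0L, cumsum(w))
    if (any(cdna < 1L | cdna > cum[length(cum)]))
        stop("cDNA position out of transcript range")
    out <- integer(length(cdna))
    for (i in seq_along(cdna)) {
        k <- findInterval(cdna[i] - 1L, cum, rightmost.closed = FALSE)
        off <- cdna[i] - cum[k] - 1L
        out[i] <- if (minus) e[k] - off else s[k] + off
    }
    out
}

#' Locate an amino-acid motif on an isoform's protein
#'
#' @param iso coding \code{TranscriptIsoform} with sequence.
#' @param motif amino-acid string, e.g. \code{"YLDL"}.
#' @return integer vector of 1-based start positions, ascending (possibly empty).
#' @export
locateMotif <- function(iso, motif) {
    if (!nzchar(motif)) stop("motif must be a non-empty amino-acid string")
    prot <- isoformProtein(iso)
    hits <- matchPattern(AAString(motif), prot)
    sort(start(hits))
}

#' Catalog of described exonic regions
#'
#' Union (overlap-merged) of the exonic intervals of every bundled isoform
#' plus the additional described alternative regions carried by the model.
#'
#' @param model a \code{GeneModel}.
#' @param gene restrict to one gene symbol (default: all).
#' @return a sorted \code{GRanges}.
#' @export
exonicRegions <- function(model, gene = NULL) {
    isoList <- if (is.null(gene)) model@isoforms else geneIsoforms(model, gene)
    exAll <- unlist(GenomicRanges::GRangesList(lapply(isoList, function(i) {
        g <- i@exons; mcols(g) <- NULL; g
    })))
    alt <- model@altRegions
    if (!is.null(gene) && length(alt) > 0L && !is.null(mcols(alt)$gene))
        alt <- alt[mcols(alt)$gene == gene]
    mcols(alt) <- NULL
    GenomicRanges::reduce(sort(c(exAll, alt)), min.gapwidth = 0L)
}

## ---- the FGFR2 fixture ---------------------------------------------------

# Exon architecture of the synthetic FGFR2 model. Only the published facts
# are contractual (strand, locus span, exon counts, protein lengths, domain
# and motif amino-acid coordinates); individual exon widths are synthetic but
# mutually consistent. All internal exon boundaries are codon-aligned, and
# exon 17 ends at codon 762 so that a junction "after exon 17" retains the
# complete kinase domain (aa 481-757) but not the YLDL motif (aa 769-772).
.FGFR2_LAYOUT <- list(
    chrom = "chr10", strand = "-",
    locusStart = 123237844L, locusEnd = 123357972L,
    exon1End = 123357900L,
    # transcript-order widths of the 18 canonical (IIIc) exons
    widths = c(200L, 300L, 150L, 147L, 162L, 120L, 141L, 141L, 150L, 144L,
               180L, 120L, 150L, 132L, 120L, 81L, 99L, 580L),
    # CDS nt contributed per exon (0 for pure-UTR exon 1)
    cdsw = c(0L, 249L, 150L, 147L, 162L, 120L, 141L, 141L, 150L, 144L,
             180L, 120L, 150L, 132L, 120L, 81L, 99L, 180L),
    utr5InExon2 = 51L,
    introns = c(5000L, 5000L, 5000L, 5000L, 5000L, 5000L, 5000L, 5000L,
                5000L, 5000L, 5000L, 5000L, 5000L, 5000L, 5000L, 5000L, 9000L),
    alt8Width = 144L, alt8Gap = 800L,      # IIIb alternative eighth exon
    insertAfterAa = 339L,                  # extra IIIb residue inside Ig-III
    c3Width = 171L, c3CdsWidth = 21L, c3Gap = 4000L  # C3 alternative last exon
)

.utrSeq <- function(n) paste0(rep_len(c("A", "C", "G", "T"), n), collapse = "")

.aaCycle <- function(n) {
    # residue alphabet without Y, so the YLDL motif can be planted uniquely
    alpha <- strsplit("ACDEFGHIKLMNPQRSTVW", "")[[1]]
    rep_len(alpha, n)
}

#' Build the packaged synthetic FGFR2 gene model
#'
#' Deterministic constructor of the three-isoform FGFR2 fixture. The model
#' satisfies the published facts: gene on the minus strand of chr10 spanning
#' 123,237,844-123,357,972 (hg19 labels); NM_000141.4 (IIIc) with 18 exons
#' encoding an 821-aa protein; NM_022970.3 (IIIb) differing only by an
#' alternative eighth exon, 822 aa; NM_001144913 (IIIb C3) lacking the first
#' exon and ending in a shorter alternative last exon whose translation lacks
#' the last 53 aa of the IIIb protein; extracellular Ig-like, heparin-binding
#' and transmembrane domains, the kinase domain at aa 481-757 and the YLDL
#' internalisation motif at aa 769-772 on the canonical protein (and nowhere
#' later); 26 described exonic regions across the extended region catalog.
#' Exon coordinates are synthetic but mutually consistent; exon labels are
#' parent-relative so shared exons keep their numbers across isoforms.
#'
#' @return a validated \code{GeneModel}.
#' @export
fgfr2GeneModel <- function() {
    L <- .FGFR2_LAYOUT
    nEx <- length(L$widths)
    # genomic layout, minus strand: exon 1 at the high-coordinate end
    ends <- integer(nEx); starts <- integer(nEx)
    ends[1] <- L$exon1End
    starts[1] <- ends[1] - L$widths[1] + 1L
    for (k in 2:nEx) {
        ends[k] <- starts[k - 1L] - L$introns[k - 1L] - 1L
        starts[k] <- ends[k] - L$widths[k] + 1L
    }
    stopifnot(starts[nEx] >= L$locusStart)

    # proteins
    aaC <- .aaCycle(821L); aaC[1] <- "M"; aaC[769:772] <- c("Y", "L", "D", "L")
    protIIIc <- paste0(aaC, collapse = "")
    i <- L$insertAfterAa
    protIIIb <- paste0(substr(protIIIc, 1L, i), "A",
                       substr(protIIIc, i + 1L, 821L))
    protC3 <- substr(protIIIb, 1L, 769L)

    cdsIIIc <- .backTranslate(paste0(protIIIc, "*"))
    cdsIIIb <- .backTranslate(paste0(protIIIb, "*"))
    stopifnot(nchar(cdsIIIc) == 2466L, nchar(cdsIIIb) == 2469L)

    # spliced sequences: UTRs are deterministic filler
    utr5a <- .utrSeq(L$widths[1])       # exon 1, all UTR
    utr5b <- .utrSeq(L$utr5InExon2)     # start of exon 2
    utr3 <- .utrSeq(L$widths[nEx] - L$cdsw[nEx])   # tail of exon 18
    seqIIIc <- paste0(utr5a, utr5b, cdsIIIc, utr3)
    seqIIIb <- paste0(utr5a, utr5b, cdsIIIb, utr3)
    c3utr3 <- .utrSeq(L$c3Width - L$c3CdsWidth)
    cdsC3 <- paste0(substr(cdsIIIb, 1L, 769L * 3L), "TAA")
    stopifnot(nchar(cdsC3) == 2310L)
    # C3 = IIIb exons 2..17 (with alt exon 8) + alternative last exon
    seqC3 <- paste0(utr5b,
                    substr(cdsIIIb, 1L, sum(L$cdsw[2:17]) + 3L),  # +3: alt8 extra codon
                    substr(cdsC3, 763L * 3L + 1L, nchar(cdsC3)),
                    c3utr3)

    isoIIIc <- transcriptIsoform("NM_000141.4", "FGFR2", L$chrom, "-",
        exonStarts = starts, exonWidths = L$widths,
        labels = as.character(1:18),
        cdsStart = L$widths[1] + L$utr5InExon2 + 1L,
        cdsEnd = L$widths[1] + L$utr5InExon2 + nchar(cdsIIIc),
        sequence = seqIIIc)

    # IIIb: alternative eighth exon placed inside intron 8, 3 nt longer
    alt8End <- starts[8] - L$alt8Gap
    alt8Start <- alt8End - L$alt8Width + 1L
    st8 <- starts; en8 <- ends; w8 <- L$widths
    st8[8] <- alt8Start; en8[8] <- alt8End; w8[8] <- L$alt8Width
    isoIIIb <- transcriptIsoform("NM_022970.3", "FGFR2", L$chrom, "-",
        exonStarts = st8, exonWidths = w8,
        labels = as.character(1:18),
        cdsStart = L$widths[1] + L$utr5InExon2 + 1L,
        cdsEnd = L$widths[1] + L$utr5InExon2 + nchar(cdsIIIb),
        sequence = seqIIIb)

    # C3: IIIb exons 2..17 plus alternative last exon inside intron 17
    c3End <- starts[17] - L$c3Gap
    c3Start <- c3End - L$c3Width + 1L
    stC <- c(st8[2:17], c3Start); wC <- c(w8[2:17], L$c3Width)
    isoC3 <- transcriptIsoform("NM_001144913", "FGFR2", L$chrom, "-",
        exonStarts = stC, exonWidths = wC,
        labels = c(as.character(2:17), "C3"),
        cdsStart = L$utr5InExon2 + 1L,
        cdsEnd = L$utr5InExon2 + nchar(cdsC3),
        sequence = seqC3)

    # additional described exonic regions (Fig-1-style extended catalog):
    # two alternative first exons (intron 1), a third alternative exon-8
    # region (intron 8), two cassette exons (introns 9 and 13), and the C2
    # alternative last exon (intron 17)
    alt <- GRanges(L$chrom, IRanges(
        start = c(starts[1] - 1500L, starts[1] - 3200L,
                  alt8Start - 1200L, starts[9] - 2000L, starts[13] - 2000L,
                  c3Start - 1500L),
        width = c(180L, 150L, 140L, 120L, 110L, 160L)), strand = "-")
    names(alt) <- c("alt_first_a", "alt_first_b", "alt_exon8_c",
                    "cassette_9", "cassette_13", "C2_last")
    mcols(alt)$gene <- "FGFR2"

    genes <- GRanges(L$chrom, IRanges(L$locusStart, L$locusEnd), strand = "-")
    names(genes) <- "FGFR2"

    mkDom <- function(shift, yldl) {
        d <- data.frame(
            name = c("Ig-like I", "heparin-binding", "Ig-like II",
                     "Ig-like III", "transmembrane", "kinase"),
            aa_start = c(43L, 162L, 172L, 264L, 371L + shift, 481L + shift),
            aa_end = c(115L, 178L, 248L, 359L + shift, 401L + shift, 757L + shift),
            dimerisation = FALSE, stringsAsFactors = FALSE)
        if (yldl > 0L)
            d <- rbind(d, data.frame(name = "YLDL", aa_start = yldl,
                                     aa_end = yldl + 3L, dimerisation = FALSE))
        d
    }
    domains <- list(
        "NM_000141.4" = mkDom(0L, 769L),
        "NM_022970.3" = mkDom(1L, 770L),
        "NM_001144913" = mkDom(1L, 0L))

    model <- new("GeneModel", genes = genes,
                 isoforms = list("NM_000141.4" = isoIIIc,
                                 "NM_022970.3" = isoIIIb,
                                 "NM_001144913" = isoC3),
                 domains = domains, build = "hg19", altRegions = alt)
    validObject(model)

    # internal consistency assertions against the published facts
    stopifnot(
        proteinLength(isoIIIc) == 821L,
        proteinLength(isoIIIb) == 822L,
        proteinLength(isoC3) == 769L,
        as.character(isoformProtein(isoC3)) ==
            substr(as.character(isoformProtein(isoIIIb)), 1L, 769L),
        identical(locateMotif(isoIIIc, "YLDL"), 769L),
        length(locateMotif(isoC3, "YLDL")) == 0L,
        length(exonicRegions(model, "FGFR2")) == 26L)
    model
}

## ---- serialization and parsing ------------------------------------------

#' Serialize a GeneModel to the fixture JSON schema
#'
#' @param model a \code{GeneModel}.
#' @param path optional file path; when NULL the JSON string is returned.
#' @export
geneModelToJson <- function(model, path = NULL) {
    isoL <- lapply(model@isoforms, function(i) {
        list(transcript_id = i@transcriptId, gene = i@gene,
             chrom = as.character(seqnames(i@exons))[1],
             strand = as.character(strand(i@exons))[1],
             exon_starts = start(i@exons), exon_widths = width(i@exons),
             exon_labels = mcols(i@exons)$exon_label,
             cds_start = i@cdsStart, cds_end = i@cdsEnd,
             sequence = if (is.null(i@sequence)) NULL else as.character(i@sequence))
    })
    genesL <- lapply(seq_along(model@genes), function(k) {
        g <- model@genes[k]
        list(symbol = names(model@genes)[k], chrom = as.character(seqnames(g)),
             start = start(g), end = end(g), strand = as.character(strand(g)))
    })
    altL <- if (length(model@altRegions)) {
        a <- model@altRegions
        list(chrom = as.character(seqnames(a)), start = start(a), end = end(a),
             name = names(a),
             gene = if (is.null(mcols(a)$gene)) NULL else mcols(a)$gene)
    } else NULL
    obj <- list(schema = "gene-model/1", build = model@build, genes = genesL,
                isoforms = unname(isoL), domains = model@domains,
                alt_regions = altL)
    json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
    if (is.null(path)) return(as.character(json))
    writeLines(as.character(json), path)
    invisible(path)
}

.geneModelFromJson <- function(txt) {
    obj <- jsonlite::fromJSON(txt, simplifyVector = TRUE, simplifyDataFrame = FALSE)
    genes <- GRanges(
        vapply(obj$genes, `[[`, "", "chrom"),
        IRanges(vapply(obj$genes, function(g) as.integer(g$start), 1L),
                vapply(obj$genes, function(g) as.integer(g$end), 1L)),
        strand = vapply(obj$genes, `[[`, "", "strand"))
    names(genes) <- vapply(obj$genes, `[[`, "", "symbol")
    isoforms <- list()
    for (iso in obj$isoforms) {
        it <- transcriptIsoform(iso$transcript_id, iso$gene, iso$chrom,
            iso$strand, as.integer(iso$exon_starts), as.integer(iso$exon_widths),
            labels = iso$exon_labels,
            cdsStart = if (is.null(iso$cds_start)) NA else iso$cds_start,
            cdsEnd = if (is.null(iso$cds_end)) NA else iso$cds_end,
            sequence = iso$sequence)
        isoforms[[iso$transcript_id]] <- it
    }
    domains <- lapply(obj$domains, function(d)
        data.frame(name = vapply(d, `[[`, "", "name"),
                   aa_start = vapply(d, function(x) as.integer(x$aa_start), 1L),
                   aa_end = vapply(d, function(x) as.integer(x$aa_end), 1L),
                   dimerisation = vapply(d, function(x) isTRUE(x$dimerisation),
                                         TRUE),
                   stringsAsFactors = FALSE))
    alt <- GRanges()
    if (!is.null(obj$alt_regions)) {
        a <- obj$alt_regions
        alt <- GRanges(a$chrom, IRanges(as.integer(a$start), as.integer(a$end)))
        names(alt) <- a$name
        if (!is.null(a$gene)) mcols(alt)$gene <- a$gene
    }
    m <- new("GeneModel", genes = genes, isoforms = isoforms, domains = domains,
             build = if (is.null(obj$build)) "custom" else obj$build,
             altRegions = alt)
    validObject(m)
    m
}

.geneModelFromGff3 <- function(path) {
    gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                   error = function(e) stop("GFF3 parse error: ",
                                            conditionMessage(e)))
    type <- as.character(gr$type)
    getParent <- function(x) vapply(x, function(p)
        if (length(p)) p[[1]] else NA_character_, "")
    genesGr <- gr[type == "gene"]
    mrna <- gr[type == "mRNA"]
    if (length(mrna) == 0L) stop("GFF3 parse error: no mRNA features")
    mrnaParent <- getParent(mrna$Parent)
    if (anyNA(mrnaParent) || !all(mrnaParent %in% genesGr$ID))
        stop("GFF3 parse error: mRNA with missing or unknown gene Parent")
    genes <- GRanges(seqnames(genesGr), IRanges(start(genesGr), end(genesGr)),
                     strand = strand(genesGr))
    geneSym <- ifelse(is.na(genesGr$Name) | !nzchar(genesGr$Name),
                      genesGr$ID, genesGr$Name)
    names(genes) <- geneSym
    isoforms <- list()
    for (k in seq_along(mrna)) {
        txId <- mrna$ID[k]
        exGr <- gr[type == "exon" & getParent(gr$Parent) == txId]
        if (length(exGr) == 0L)
            stop("validation error: mRNA ", txId, " has no exon features")
        cdsGr <- gr[type == "CDS" & getParent(gr$Parent) == txId]
        minus <- as.character(strand(mrna[k])) == "-"
        exGr <- if (minus) exGr[order(start(exGr), decreasing = TRUE)]
                else exGr[order(start(exGr))]
        geneOfTx <- geneSym[match(mrnaParent[k], genesGr$ID)]
        cdsStart <- NA_integer_; cdsEnd <- NA_integer_
        if (length(cdsGr)) {
            # CDS bounds in transcript coordinates
            bounds <- c(start(cdsGr), end(cdsGr))
            iso0 <- transcriptIsoform(txId, geneOfTx,
                as.character(seqnames(exGr))[1], if (minus) "-" else "+",
                start(exGr), width(exGr))
            mp <- genomicToTranscript(iso0, bounds)
            if (any(mp$region != "exon"))
                stop("validation error: CDS of ", txId, " outside its exons")
            cdsStart <- min(mp$cdna); cdsEnd <- max(mp$cdna)
            if ((cdsEnd - cdsStart + 1L) %% 3L != 0L)
                stop("validation error: CDS length of ", txId,
                     " not divisible by 3")
        }
        isoforms[[txId]] <- transcriptIsoform(txId, geneOfTx,
            as.character(seqnames(exGr))[1], if (minus) "-" else "+",
            start(exGr), width(exGr),
            cdsStart = cdsStart, cdsEnd = cdsEnd)
    }
    m <- new("GeneModel", genes = genes, isoforms = isoforms,
             domains = list(), build = "custom")
    validObject(m)
    m
}

#' Load a GeneModel from GFF3 or fixture JSON
#'
#' Auto-detects the format: content starting with \code{\{} is parsed against
#' the fixture JSON schema (the format written by \code{geneModelToJson});
#' anything else is read as GFF3 with gene/mRNA/exon/CDS features via
#' rtracklayer. GFF3 1-based inclusive coordinates are kept in the package's
#' 1-based closed convention; exons are sorted into transcript order by
#' strand.
#'
#' @param path file path.
#' @return a validated \code{GeneModel}.
#' @export
loadGeneModel <- function(path) {
    head <- readLines(path, n = 1L, warn = FALSE)
    if (length(head) && grepl("^\\s*\\{", head))
        .geneModelFromJson(paste(readLines(path, warn = FALSE), collapse = "\n"))
    else
        .geneModelFromGff3(path)
}
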