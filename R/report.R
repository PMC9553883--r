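## Clinical report rendering: fusion/rearrangement nomenclature, RNA and
## DNA report assembly, and the mandatory-field validator.

# compact exon-code letters: first letter of each symbol, upper-case; when
# both symbols share the initial, the first differing letter is appended
.exonCodeLetters <- function(g5, g3) {
    l5 <- toupper(substr(g5, 1L, 1L)); l3 <- toupper(substr(g3, 1L, 1L))
    if (l5 != l3) return(c(l5, l3))
    n <- max(nchar(g5), nchar(g3))
    for (k in 2:n) {
        a <- toupper(substr(g5, k, k)); b <- toupper(substr(g3, k, k))
        if (a != b || !nzchar(a) || !nzchar(b))
            return(c(paste0(l5, a), paste0(l3, b)))
    }
    c(paste0(l5, "5"), paste0(l3, "3"))
}

#' Display label for a fusion or rearrangement
#'
#' In-gene fusions render as \code{"GENE5::GENE3 (F17A12)"}: the gene pair
#' plus a compact code built from gene initials and junction exon numbers.
#' Partnerless events render as a rearrangement phrase naming only the
#' driver region.
#'
#' @param gene5 driver gene symbol.
#' @param exon5 driver junction exon (number or label).
#' @param gene3 partner symbol, or NA/NULL for a partnerless rearrangement.
#' @param exon3 partner junction exon.
#' @param region driver region phrase used for the partnerless rendering
#'   (default \code{"intron 17"}).
#' @return character label.
#' @export
fusionLabel <- function(gene5, exon5, gene3 = NULL, exon3 = NULL,
                        region = "intron 17") {
    if (is.null(gene3) || is.na(gene3) || !nzchar(gene3))
        return(sprintf("%s rearrangement (%s), no partner gene identified",
                       gene5, region))
    code <- .exonCodeLetters(gene5, gene3)
    sprintf("%s::%s (%s%s%s%s)", gene5, gene3, code[1], exon5, code[2], exon3)
}

#' Parse a fusion label back to its components
#'
#' @param label a string produced by \code{fusionLabel}.
#' @return list with \code{gene5}, \code{exon5}, \code{gene3}, \code{exon3},
#'   or NULL when the label is a partnerless rearrangement phrase.
#' @export
parseFusionLabel <- function(label) {
    m <- regmatches(label,
        regexec("^([A-Za-z0-9-]+)::([A-Za-z0-9-]+) \\([A-Z]+([0-9]+)[A-Z]+([0-9]+)\\)$",
                label))[[1]]
    if (length(m) == 0L) return(NULL)
    list(gene5 = m[2], exon5 = m[4], gene3 = m[3], exon3 = m[5])
}

.RNA_MANDATORY <- c("assay_description", "quality", "reads",
                    "fusion_read_ratio", "genes", "junction_exons",
                    "frame_statement", "domain_statement")
.DNA_MANDATORY <- c("assay_description", "quality", "reads",
                    "translocation_read_ratio", "genes", "breakpoints",
                    "genome_build", "frame_domain_estimate")

.checkMeta <- function(meta) {
    need <- c("assay_description", "tumour_cell_content",
              "nucleic_acid_quality", "library_quality")
    missing <- setdiff(need, names(meta))
    if (length(missing))
        stop("cannot render report; missing metadata field(s): ",
             paste(missing, collapse = ", "))
}

.pickRecord <- function(ann) {
    rec <- ann@records
    informative <- rec[rec$frame != "indeterminate", , drop = FALSE]
    if (nrow(informative)) informative[1, ] else rec[1, ]
}

#' Render a clinical RNA fusion report
#'
#' Includes the five mandated items: read counts (split/paired), the
#' fusion-read ratio, gene names with transcript IDs, the junction exons,
#' and the frame plus domain-integrity statement.
#'
#' @param junction the reported \code{FusionJunction}.
#' @param ann its \code{FusionAnnotation}.
#' @param meta named list with \code{assay_description},
#'   \code{tumour_cell_content}, \code{nucleic_acid_quality},
#'   \code{library_quality}.
#' @return a \code{ClinicalReport}.
#' @export
renderRnaReport <- function(junction, ann, meta) {
    .checkMeta(meta)
    missing <- character()
    if (!nzchar(junction@tx5) || is.na(junction@tx5))
        missing <- c(missing, "tx5")
    if (!nzchar(junction@tx3) || is.na(junction@tx3))
        missing <- c(missing, "tx3")
    if (length(missing))
        stop("cannot render report; missing transcript ID(s): ",
             paste(missing, collapse = ", "))
    ratio <- fusionReadRatio(junction@evidence)   # errors on zero evidence
    rec <- .pickRecord(ann)
    frameTxt <- switch(rec$frame,
        in_frame = "The fusion is in-frame.",
        out_of_frame = "The fusion is not in-frame.",
        no_cds_3p = paste("The junction lies upstream of the partner start",
                          "codon; no partner coding sequence is gained."),
        "The reading frame could not be determined.")
    domainTxt <- sprintf(
        "The FGFR2 tyrosine kinase domain is %s; oncogenic mechanism: %s.",
        if (rec$kinase_retained) "intact" else "disrupted",
        gsub("_", " ", rec$mechanism))
    fields <- list(
        level = "RNA",
        assay_description = meta$assay_description,
        quality = list(tumour_cell_content = meta$tumour_cell_content,
                       nucleic_acid_quality = meta$nucleic_acid_quality,
                       library_quality = meta$library_quality),
        label = fusionLabel(junction@gene5, junction@exon5, junction@gene3,
                            junction@exon3),
        reads = list(split = unname(readCounts(junction@evidence)["split"]),
                     paired = unname(readCounts(junction@evidence)["spanning"])),
        fusion_read_ratio = ratio,
        genes = list(gene5 = junction@gene5, tx5 = junction@tx5,
                     gene3 = junction@gene3, tx3 = junction@tx3),
        junction_exons = list(exon5 = junction@exon5, offset5 = junction@offset5,
                              exon3 = junction@exon3, offset3 = junction@offset3),
        frame_statement = frameTxt,
        domain_statement = domainTxt,
        isoform_conflict = ann@conflict,
        vicc = list(
            five_prime = list(transcript = junction@tx5, exon = junction@exon5,
                              offset = junction@offset5),
            three_prime = list(transcript = junction@tx3, exon = junction@exon3,
                               offset = junction@offset3)),
        footnote = paste("Fusion-read ratio = (split + spanning pairs) /",
                         "(split + spanning pairs + wild-type reads)."))
    new("ClinicalReport", level = "RNA", fields = fields,
        markdown = .reportMd(fields))
}

#' Render a clinical DNA translocation report
#'
#' Includes read counts, the translocation-read ratio, involved gene names,
#' chromosomal breakpoint positions, the genome reference build, and a
#' frame/domain estimate; the estimate carries a mandatory cautious
#' qualifier whenever the mechanism is indeterminate at DNA level.
#'
#' @param event the reported \code{BreakpointEvent}.
#' @param ann its \code{FusionAnnotation}.
#' @param meta as in \code{renderRnaReport}, plus mandatory \code{build}.
#' @param model optional \code{GeneModel} used to name the involved genes.
#' @return a \code{ClinicalReport}.
#' @export
renderDnaReport <- function(event, ann, meta, model = NULL) {
    .checkMeta(meta)
    if (is.null(meta$build) || !nzchar(meta$build))
        stop("cannot render report; missing metadata field(s): build")
    b5 <- event@breakend5
    if (is.na(b5@pos)) stop("cannot render report; missing breakpoint coordinates")
    ratio <- fusionReadRatio(event@evidence)
    rec <- .pickRecord(ann)
    gene5 <- if (!is.null(model)) .geneAt(model, b5@chrom, b5@pos) else "FGFR2"
    gene3 <- NA_character_
    bp3 <- NULL
    # bridged or intergenic events are reported as rearrangements without a
    # partner gene, even when a candidate second breakend exists
    unresolved <- !is.na(event@insertSeq) ||
        event@partnerStatus %in% c("ambiguous", "unmapped", "intergenic")
    if (!is.null(event@breakend3)) {
        bp3 <- sprintf("%s:%d", event@breakend3@chrom, event@breakend3@pos)
        if (!is.null(model) && !unresolved)
            gene3 <- .geneAt(model, event@breakend3@chrom, event@breakend3@pos)
        if (identical(gene3, gene5)) gene3 <- NA_character_
    }
    cautious <- identical(rec$mechanism, "indeterminate")
    estimate <- sprintf(
        "%sframe: %s; kinase domain %s; mechanism: %s.",
        if (cautious) paste("DNA-level estimate, to be interpreted with",
                            "caution (partner sequence content unresolved); ")
        else "",
        rec$frame, if (rec$kinase_retained) "retained" else "lost",
        gsub("_", " ", rec$mechanism))
    exonOf <- function(region) {
        if (is.na(region) || !grepl("[0-9]", region)) return("?")
        sub("[^0-9]*([0-9]+).*", "\\1", region)
    }
    iscn <- if (!is.null(bp3))
        sprintf("t(%s;%s)(%d;%d)", sub("chr", "", b5@chrom),
                sub("chr", "", event@breakend3@chrom), b5@pos,
                event@breakend3@pos)
    else sprintf("rearrangement(%s)(%d)", sub("chr", "", b5@chrom), b5@pos)
    hgvs <- if (!is.null(bp3))
        sprintf("g.[%s:%d::%s]", b5@chrom, b5@pos, bp3)
    else sprintf("g.%s:%d_?", b5@chrom, b5@pos)
    fields <- list(
        level = "DNA",
        assay_description = meta$assay_description,
        quality = list(tumour_cell_content = meta$tumour_cell_content,
                       nucleic_acid_quality = meta$nucleic_acid_quality,
                       library_quality = meta$library_quality),
        label = fusionLabel(gene5, exonOf(rec$region5), gene3,
                            exonOf(rec$region3), region = rec$region5),
        reads = list(split = unname(readCounts(event@evidence)["split"]),
                     paired = unname(readCounts(event@evidence)["spanning"])),
        translocation_read_ratio = ratio,
        genes = list(gene5 = gene5, gene3 = gene3),
        breakpoints = list(five_prime = sprintf("%s:%d", b5@chrom, b5@pos),
                           three_prime = bp3),
        genome_build = meta$build,
        iscn = iscn, hgvs = hgvs,
        frame_domain_estimate = estimate,
        isoform_conflict = ann@conflict)
    new("ClinicalReport", level = "DNA", fields = fields,
        markdown = .reportMd(fields))
}

.reportMd <- function(f) {
    md <- c(sprintf("# Clinical %s fusion/translocation report", f$level),
            "", sprintf("**Finding:** %s", f$label), "",
            sprintf("- Assay: %s", f$assay_description),
            sprintf("- Tumour cell content: %s", f$quality$tumour_cell_content),
            sprintf("- Nucleic acid quality: %s", f$quality$nucleic_acid_quality),
            sprintf("- Library quality: %s", f$quality$library_quality),
            sprintf("- Reads (split/paired): %d / %d", f$reads$split,
                    f$reads$paired))
    if (!is.null(f$fusion_read_ratio))
        md <- c(md, sprintf("- Fusion-read ratio: %.3f", f$fusion_read_ratio),
                sprintf("- Genes: %s (%s) :: %s (%s)", f$genes$gene5,
                        f$genes$tx5, f$genes$gene3, f$genes$tx3),
                sprintf("- Junction exons: %s (+%d) :: %s (+%d)",
                        f$junction_exons$exon5, f$junction_exons$offset5,
                        f$junction_exons$exon3, f$junction_exons$offset3),
                sprintf("- %s", f$frame_statement),
                sprintf("- %s", f$domain_statement))
    if (!is.null(f$translocation_read_ratio))
        md <- c(md, sprintf("- Translocation-read ratio: %.3f",
                            f$translocation_read_ratio),
                sprintf("- Breakpoints: %s :: %s", f$breakpoints$five_prime,
                        if (is.null(f$breakpoints$three_prime)) "unresolved"
                        else f$breakpoints$three_prime),
                sprintf("- Reference build: %s", f$genome_build),
                sprintf("- ISCN: %s; HGVS: %s", f$iscn, f$hgvs),
                sprintf("- %s", f$frame_domain_estimate))
    if (isTRUE(f$isoform_conflict))
        md <- c(md, "- NOTE: isoform-dependent interpretation conflict; see records.")
    if (!is.null(f$footnote)) md <- c(md, "", f$footnote)
    md
}

#' Validate the mandatory fields of a rendered report
#'
#' RNA reports must state read counts, the fusion-read ratio, gene names
#' with transcript IDs, junction exons and the frame/domain statements; DNA
#' reports must state read counts, the translocation-read ratio, gene
#' names, breakpoint positions, the genome build and the frame/domain
#' estimate.
#'
#' @param report a \code{ClinicalReport}, or a named list of its fields.
#' @return list with \code{valid} (logical) and \code{missing} (character).
#' @export
validateReport <- function(report) {
    f <- if (is(report, "ClinicalReport")) report@fields else report
    level <- f$level
    if (is.null(level)) return(list(valid = FALSE, missing = "level"))
    need <- if (identical(level, "RNA")) .RNA_MANDATORY else .DNA_MANDATORY
    present <- vapply(need, function(k) {
        v <- f[[k]]
        !is.null(v) && !(is.character(v) && !any(nzchar(v)))
    }, TRUE)
    list(valid = all(present), missing = need[!present])
}

#' Write a report as JSON
#' @param report a \code{ClinicalReport}.
#' @param path output path; when NULL the JSON string is returned.
#' @export
reportToJson <- function(report, path = NULL) {
    json <- jsonlite::toJSON(report@fields, auto_unbox = TRUE, digits = NA,
                             null = "null", na = "null")
    if (is.null(path)) return(as.character(json))
    writeLines(as.character(json), path)
    invisible(path)
}
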