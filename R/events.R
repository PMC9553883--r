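#' Construct a ReadEvidence object
#' @param split,spanning,wildtype non-negative read counts.
#' @export
readEvidence <- function(split = 0L, spanning = 0L, wildtype = 0L) {
    new("ReadEvidence", splitReads = as.integer(split),
        spanningPairs = as.integer(spanning), wildtypeReads = as.integer(wildtype))
}

#' Construct a Breakend
#' @param chrom chromosome; \code{pos} 1-based position;
#'   \code{orientation} \code{"left"} or \code{"right"} (genomic side retained).
#' @export
breakend <- function(chrom, pos, orientation = "right") {
    new("Breakend", chrom = chrom, pos = as.integer(pos),
        orientation = orientation)
}

#' Construct a BreakpointEvent
#'
#' The driver (FGFR2) side is always side 5'; ingestion normalizes record
#' order so downstream logic can assume it.
#'
#' @param id event id.
#' @param breakend5 driver-side \code{Breakend}.
#' @param breakend3 partner-side \code{Breakend} or NULL.
#' @param partnerStatus \code{"mapped"}, \code{"unmapped"}, \code{"intergenic"}
#'   or \code{"ambiguous"}.
#' @param insertSeq,insertOrigin optional bridging insert and its mapped
#'   origin (\code{"chrN:pos"} or \code{"repeat:<family>"}).
#' @param evidence a \code{ReadEvidence}.
#' @export
breakpointEvent <- function(id, breakend5, breakend3 = NULL,
                            partnerStatus = if (is.null(breakend3)) "unmapped"
                                            else "mapped",
                            insertSeq = NA_character_,
                            insertOrigin = NA_character_,
                            evidence = readEvidence()) {
    new("BreakpointEvent", id = id, breakend5 = breakend5,
        breakend3 = breakend3, partnerStatus = partnerStatus,
        insertSeq = insertSeq, insertOrigin = insertOrigin,
        evidence = evidence)
}

#' Construct a FusionJunction
#' @param id identifier.
#' @param gene5,tx5,exon5,offset5 driver side.
#' @param gene3,tx3,exon3,offset3 partner side.
#' @param evidence a \code{ReadEvidence}.
#' @param novel5,novel3 transcript-unknown flags.
#' @export
fusionJunction <- function(id, gene5, tx5, exon5, offset5 = 0L,
                           gene3, tx3, exon3, offset3 = 0L,
                           evidence = readEvidence(),
                           novel5 = FALSE, novel3 = FALSE) {
    new("FusionJunction", id = id,
        gene5 = gene5, tx5 = tx5, exon5 = as.character(exon5),
        offset5 = as.integer(offset5),
        gene3 = gene3, tx3 = tx3, exon3 = as.character(exon3),
        offset3 = as.integer(offset3),
        novel5 = novel5, novel3 = novel3, evidence = evidence)
}

#' Fusion-read ratio
#'
#' Abundance of fusion-supporting reads relative to all reads at the
#' junction: (split + spanning) / (split + spanning + wildtype).
#'
#' @param ev a \code{ReadEvidence}.
#' @return fraction in [0, 1].
#' @export
fusionReadRatio <- function(ev) {
    stopifnot(is(ev, "ReadEvidence"))
    num <- ev@splitReads + ev@spanningPairs
    den <- num + ev@wildtypeReads
    if (den == 0L)
        stop("undefined fusion-read ratio: no reads at the junction")
    num / den
}

## ---- BEDPE I/O -----------------------------------------------------------

.BEDPE_EXTRA <- c("insert_seq", "insert_origin", "split", "spanning",
                  "wildtype", "orient1", "orient2", "partner_status")

#' Read DNA breakpoints from BEDPE
#'
#' Standard 10-column BEDPE (chrom1, start1, end1, chrom2, start2, end2,
#' name, score, strand1, strand2), 0-based half-open on disk and converted to
#' the package's 1-based convention on input. A missing partner is encoded by
#' \code{chrom2 = "."}. Optional extra columns carry the bridging insert
#' sequence/origin, read counts, breakend orientations and partner status.
#'
#' @param path file path (or connection) to a BEDPE file.
#' @return list of \code{BreakpointEvent}.
#' @export
readBedpe <- function(path) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    if (length(lines) == 0L) return(list())
    out <- vector("list", length(lines))
    for (i in seq_along(lines)) {
        f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
        if (length(f) < 10L)
            stop("BEDPE format error at line ", i, ": expected >= 10 columns, got ",
                 length(f))
        extra <- setNames(rep(NA_character_, length(.BEDPE_EXTRA)), .BEDPE_EXTRA)
        if (length(f) > 10L) {
            got <- f[11:min(length(f), 10L + length(.BEDPE_EXTRA))]
            extra[seq_along(got)] <- got
        }
        numOr0 <- function(x) if (is.na(x) || x == "." || !nzchar(x)) 0L
                              else as.integer(unname(x))
        strOrNA <- function(x) if (is.na(x) || x == "." || !nzchar(x))
                               NA_character_ else unname(x)
        id <- if (f[7] == "." || !nzchar(f[7])) sprintf("bp_%04d", i) else f[7]
        be5 <- breakend(f[1], as.integer(f[2]) + 1L,
                        orientation = if (is.na(strOrNA(extra["orient1"])))
                            "right" else extra[["orient1"]])
        be3 <- NULL
        status <- strOrNA(extra["partner_status"])
        if (f[4] != ".") {
            be3 <- breakend(f[4], as.integer(f[5]) + 1L,
                            orientation = if (is.na(strOrNA(extra["orient2"])))
                                "left" else extra[["orient2"]])
            if (is.na(status)) status <- "mapped"
        } else if (is.na(status)) status <- "unmapped"
        out[[i]] <- breakpointEvent(id, be5, be3, partnerStatus = status,
            insertSeq = strOrNA(extra["insert_seq"]),
            insertOrigin = strOrNA(extra["insert_origin"]),
            evidence = readEvidence(numOr0(extra["split"]),
                                    numOr0(extra["spanning"]),
                                    numOr0(extra["wildtype"])))
    }
    out
}

#' Write BreakpointEvents as BEDPE
#' @param events list of \code{BreakpointEvent}.
#' @param path output path.
#' @export
writeBedpe <- function(events, path) {
    rows <- vapply(events, function(ev) {
        b5 <- ev@breakend5
        c2 <- "."; s2 <- 0L; e2 <- 0L; or2 <- "."
        if (!is.null(ev@breakend3)) {
            c2 <- ev@breakend3@chrom
            s2 <- ev@breakend3@pos - 1L; e2 <- ev@breakend3@pos
            or2 <- ev@breakend3@orientation
        }
        na2dot <- function(x) if (is.na(x)) "." else as.character(x)
        paste(c(b5@chrom, b5@pos - 1L, b5@pos, c2, s2, e2, ev@id, 0L, ".", ".",
                na2dot(ev@insertSeq), na2dot(ev@insertOrigin),
                ev@evidence@splitReads, ev@evidence@spanningPairs,
                ev@evidence@wildtypeReads, b5@orientation, or2,
                ev@partnerStatus), collapse = "\t")
    }, "")
    writeLines(rows, path)
    invisible(path)
}

## ---- junction TSV I/O ----------------------------------------------------

.JUNCTION_COLS <- c("id", "gene5", "tx5", "exon5", "offset5",
                    "gene3", "tx3", "exon3", "offset3",
                    "split", "spanning", "wildtype")

#' Read RNA fusion junctions from TSV
#'
#' Columns: id, gene5, tx5, exon5, offset5, gene3, tx3, exon3, offset3,
#' split, spanning, wildtype (header required). Rows referencing transcript
#' ids absent from \code{model} are flagged novel, not rejected; rows with
#' zero fusion evidence get a warning attribute \code{"evidence_free"}.
#'
#' @param path TSV path.
#' @param model optional \code{GeneModel} used to flag novel transcripts.
#' @return list of \code{FusionJunction}.
#' @export
readJunctions <- function(path, model = NULL) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (nrow(df) == 0L) return(list())
    missing <- setdiff(.JUNCTION_COLS, names(df))
    if (length(missing))
        stop("junction TSV missing column(s): ", paste(missing, collapse = ", "))
    if (any(df$offset5 < 0 | df$offset3 < 0, na.rm = TRUE))
        stop("validation error: negative junction offsets")
    if (any(df$split < 0 | df$spanning < 0 | df$wildtype < 0, na.rm = TRUE))
        stop("validation error: negative read counts")
    known <- if (is.null(model)) NULL else names(model@isoforms)
    out <- vector("list", nrow(df))
    evidenceFree <- character()
    for (i in seq_len(nrow(df))) {
        r <- df[i, ]
        j <- fusionJunction(as.character(r$id), r$gene5, r$tx5, r$exon5,
            r$offset5, r$gene3, r$tx3, r$exon3, r$offset3,
            evidence = readEvidence(r$split, r$spanning, r$wildtype),
            novel5 = !is.null(known) && !r$tx5 %in% known,
            novel3 = !is.null(known) && !r$tx3 %in% known)
        if (r$split == 0L && r$spanning == 0L)
            evidenceFree <- c(evidenceFree, j@id)
        out[[i]] <- j
    }
    if (length(evidenceFree)) {
        warning("evidence-free junction call(s): ",
                paste(evidenceFree, collapse = ", "))
        attr(out, "evidence_free") <- evidenceFree
    }
    out
}

#' Write FusionJunctions as TSV
#' @param junctions list of \code{FusionJunction}.
#' @param path output path.
#' @export
writeJunctions <- function(junctions, path) {
    df <- do.call(rbind, lapply(junctions, function(j)
        data.frame(id = j@id, gene5 = j@gene5, tx5 = j@tx5, exon5 = j@exon5,
                   offset5 = j@offset5, gene3 = j@gene3, tx3 = j@tx3,
                   exon3 = j@exon3, offset3 = j@offset3,
                   split = j@evidence@splitReads,
                   spanning = j@evidence@spanningPairs,
                   wildtype = j@evidence@wildtypeReads,
                   stringsAsFactors = FALSE)))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
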