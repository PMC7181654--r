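#' @importFrom GenomicRanges GRanges seqnames strand start end width
#'   findOverlaps distanceToNearest pintersect reduce mcols mcols<-
#' @importFrom IRanges IRanges ranges overlapsAny subsetByOverlaps
#' @importFrom S4Vectors queryHits subjectHits mcols
NULL

.normClass <- function(x) {
    x <- tolower(x)
    out <- rep(NA_character_, length(x))
    out[x %in% c("protein_coding", "protein-coding", "coding")] <-
        "protein_coding"
    out[x %in% c("lncrna", "lincrna", "long_noncoding", "antisense",
                 "lnc_rna")] <- "lncRNA"
    out
}

#' Read a gene annotation and build gene models
#'
#' Parses a GTF (1-based, inclusive) or BED12 (0-based, half-open) annotation
#' into a [GenomicRanges::GRanges] of gene bodies with metadata columns
#' `gene_id`, `gene_class` (`protein_coding` or `lncRNA`) and `n_exons`.
#' Conversion between the file's coordinate convention and the internal
#' representation is handled entirely by \pkg{rtracklayer}; a GTF gene
#' spanning 1-based `[101, 200]` yields a gene model of width (length) 100.
#'
#' Genes with several transcripts are collapsed to the union of their ranges
#' (one gene body per gene) with a warning; gene records without exon rows
#' get a single exon covering the gene body, with a warning. Records without
#' a strand and genes whose class is neither protein-coding nor lncRNA (and
#' not supplied in `classMap`) are dropped with a warning.
#'
#' @param path annotation file (`.gtf`/`.gff` or `.bed`).
#' @param format `"auto"` (from the extension), `"gtf"` or `"bed"`.
#' @param classMap optional named character vector, gene_id -> class, used
#'   when the file carries no `gene_biotype` attribute (e.g. BED12).
#' @return `GRanges` of gene bodies, one row per gene.
#' @examples
#' bundle <- simulateAnnotation(
#'     list(geometrySpec("XH", overlap = 599)), dir = tempdir())
#' genes <- readAnnotation(bundle$paths["gtf"])
#' table(genes$gene_class)
#' @export
readAnnotation <- function(path, format = c("auto", "gtf", "bed"),
                           classMap = NULL) {
    format <- match.arg(format)
    if (format == "auto")
        format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed"
                  else "gtf"
    gr <- rtracklayer::import(path, format = format)
    if (format == "bed") {
        ids <- if (!is.null(gr$name)) gr$name else
            paste0("gene", seq_along(gr))
        cls <- rep(NA_character_, length(gr))
        bodies <- gr
        exonCount <- if (!is.null(gr$blocks))
            lengths(gr$blocks) else rep(1L, length(gr))
    } else {
        if (is.null(gr$gene_id))
            stop("annotation has no gene_id attribute")
        type <- as.character(gr$type)
        src <- if (any(type == "gene")) gr[type == "gene"] else gr
        ids <- src$gene_id
        btCol <- intersect(c("gene_biotype", "gene_type"),
                           colnames(mcols(src)))
        cls <- if (length(btCol)) as.character(mcols(src)[[btCol[1]]])
               else rep(NA_character_, length(src))
        bodies <- src
        ex <- gr[type == "exon"]
        exonCount <- as.integer(table(factor(ex$gene_id, levels = ids)))
        noExon <- exonCount == 0L
        if (any(noExon)) {
            warning(sum(noExon), " gene(s) without exon records; ",
                    "using the gene body as a single exon")
            exonCount[noExon] <- 1L
        }
    }
    # collapse duplicated gene ids (multi-transcript) to the range union
    if (anyDuplicated(ids)) {
        warning("collapsing ", sum(duplicated(ids)),
                " extra record(s) of multi-transcript genes to gene-body",
                " unions")
        keep <- !duplicated(ids)
        for (id in unique(ids[duplicated(ids)])) {
            i <- which(ids == id)
            r <- range(bodies[i])
            bodies[i[1]] <- r[1]
        }
        bodies <- bodies[keep]
        exonCount <- exonCount[keep]
        cls <- cls[keep]
        ids <- ids[keep]
    }
    cls <- .normClass(cls)
    if (!is.null(classMap)) {
        hit <- ids %in% names(classMap)
        cls[hit] <- .normClass(classMap[ids[hit]])
    }
    noStrand <- as.character(strand(bodies)) == "*"
    if (any(noStrand)) {
        warning(sum(noStrand), " record(s) without strand rejected")
        bodies <- bodies[!noStrand]; ids <- ids[!noStrand]
        cls <- cls[!noStrand]; exonCount <- exonCount[!noStrand]
    }
    unk <- is.na(cls)
    if (any(unk)) {
        warning(sum(unk), " gene(s) of unknown class excluded")
        bodies <- bodies[!unk]; ids <- ids[!unk]
        exonCount <- exonCount[!unk]; cls <- cls[!unk]
    }
    out <- GRanges(seqnames(bodies), ranges(bodies), strand(bodies))
    mcols(out) <- DataFrame(gene_id = ids, gene_class = cls,
                            n_exons = exonCount)
    names(out) <- ids
    out
}

#' Overlap and gap between two gene bodies
#'
#' Returns the length of the interval intersection of two gene bodies and
#' the gap between them (`0` when they overlap or are adjacent). Symmetric
#' in its arguments; errors if the genes lie on different chromosomes.
#'
#' @param a,b single-range `GRanges` gene models.
#' @return named numeric vector `c(overlap_bp =, distance_bp =)`.
#' @examples
#' a <- GenomicRanges::GRanges("chr1:1-100")
#' b <- GenomicRanges::GRanges("chr1:51-150")
#' overlapAndDistance(a, b)  # 50 bp overlap, gap 0
#' @export
overlapAndDistance <- function(a, b) {
    stopifnot(length(a) == 1L, length(b) == 1L)
    if (as.character(seqnames(a)) != as.character(seqnames(b)))
        stop("genes lie on different chromosomes")
    ov <- max(0L, min(end(a), end(b)) - max(start(a), start(b)) + 1L)
    gap <- if (ov > 0L) 0L else max(start(a), start(b)) -
        min(end(a), end(b)) - 1L
    c(overlap_bp = ov, distance_bp = max(0L, gap))
}

# five-prime coordinate of a gene body
.fivePrime <- function(st, start, end) ifelse(st == "+", start, end)
.threePrime <- function(st, start, end) ifelse(st == "+", end, start)

# Scalar rule table: classify one lncRNA against its selected partner.
# Returns list(biotype, overlap, distance, five_prime_overlap, ambiguous).
.classifyPair <- function(ls, le, lstrand, cs, ce, cstrand, genicWindow) {
    ov <- max(0L, min(le, ce) - max(ls, cs) + 1L)
    gap <- if (ov > 0L) 0L else max(0L, max(ls, cs) - min(le, ce) - 1L)
    amb <- FALSE
    if (ov > 0L) {
        if (lstrand == cstrand) {
            bt <- "unclassified_sense_overlap"
            f5 <- FALSE
        } else if (ls >= cs && le <= ce) {
            bt <- "XI"; f5 <- FALSE
        } else if (cs >= ls && ce <= le) {
            bt <- "XO"; f5 <- FALSE
        } else {
            oS <- max(ls, cs); oE <- min(le, ce)
            l5 <- .fivePrime(lstrand, ls, le)
            c5 <- .fivePrime(cstrand, cs, ce)
            in5l <- l5 >= oS && l5 <= oE
            in5c <- c5 >= oS && c5 <= oE
            if (in5l && in5c) { bt <- "XH"; f5 <- TRUE }
            else if (!in5l && !in5c) { bt <- "XT"; f5 <- FALSE }
            else { # offset geometry with mixed ends: follow the lncRNA's end
                bt <- if (in5l) "XH" else "XT"
                f5 <- FALSE; amb <- TRUE
            }
        }
    } else if (gap > genicWindow) {
        bt <- "IG"; f5 <- FALSE
    } else if (lstrand == cstrand) {
        c3 <- .threePrime(cstrand, cs, ce)
        downstream <- if (cstrand == "+") ls > c3 else le < c3
        bt <- if (downstream) "SD" else "SU"
        f5 <- FALSE
    } else {
        # antisense, non-overlapping, within the window: divergent pairs
        # face 5' to 5' (XH), convergent pairs 3' to 3' (XT)
        lncLeft <- le < cs
        facing5 <- if (lncLeft) lstrand == "-" else lstrand == "+"
        bt <- if (facing5) "XH" else "XT"
        f5 <- FALSE
    }
    list(biotype = bt, overlap = ov, distance = gap,
         five_prime_overlap = f5, ambiguous = amb)
}

#' Select the partner coding gene for an lncRNA
#'
#' Chooses, in priority order: (1) the coding gene with the largest gene-body
#' overlap; (2) among non-overlapping candidates within `genicWindow`, the
#' one at the smallest gene-body gap; ties broken by lexicographically
#' smallest `gene_id`. Returns `NA` if no candidate overlaps or lies within
#' the window.
#'
#' @param lnc single-range `GRanges` lncRNA gene model.
#' @param candidates `GRanges` of coding gene models (same chromosome
#'   candidates are considered; others are ignored).
#' @param genicWindow maximum gap, in bp, for a genic partner (default 5000).
#' @return the `gene_id` of the chosen partner, or `NA_character_`.
#' @examples
#' lnc <- GenomicRanges::GRanges("chr1:1000-1999", strand = "+")
#' cands <- GenomicRanges::GRanges(c("chr1:2100-2999", "chr1:4000-4999"),
#'                                 strand = "+")
#' cands$gene_id <- c("geneA", "geneB")
#' pairPartner(lnc, cands)  # geneA (100 bp away beats 2 kb)
#' @export
pairPartner <- function(lnc, candidates, genicWindow = 5000) {
    stopifnot(length(lnc) == 1L)
    if (!length(candidates)) return(NA_character_)
    same <- as.character(seqnames(candidates)) ==
        as.character(seqnames(lnc))
    candidates <- candidates[same]
    if (!length(candidates)) return(NA_character_)
    ov <- pmax(0L, pmin(end(candidates), end(lnc)) -
                   pmax(start(candidates), start(lnc)) + 1L)
    ids <- candidates$gene_id
    if (any(ov > 0L)) {
        best <- which(ov == max(ov))
        return(ids[best][order(ids[best])][1L])
    }
    gap <- pmax(start(candidates), start(lnc)) -
        pmin(end(candidates), end(lnc)) - 1L
    gap <- pmax(gap, 0L)
    ok <- gap <= genicWindow
    if (!any(ok)) return(NA_character_)
    gap <- gap[ok]; ids <- ids[ok]
    best <- which(gap == min(gap))
    ids[best][order(ids[best])][1L]
}

#' Classify lncRNA genes into positional biotypes
#'
#' Assigns each lncRNA one of the seven positional biotypes relative to its
#' selected partner coding gene (see [pairPartner()]): antisense
#' geometries `XI` (lncRNA inside the coding gene body), `XO` (lncRNA
#' containing it), `XH` (divergent; overlapping head-to-head at both 5' ends,
#' or non-overlapping 5'-facing within the genic window) and `XT`
#' (convergent; the tail-to-tail mirror image); same-strand non-overlapping
#' geometries `SD` (lncRNA downstream of the coding 3' end) and `SU`
#' (upstream of the coding 5' end) within the window; and `IG` (intergenic,
#' nearest coding gene more than `genicWindow` bp away). Same-strand
#' overlaps fall outside the seven-label scheme and are reported explicitly
#' as `unclassified_sense_overlap`, never silently as `IG`. Classification
#' depends on gene-body geometry only, not exon structure.
#'
#' The genic window is inclusive: a gap of exactly `genicWindow` bp counts
#' as genic; `genicWindow + 1` is intergenic.
#'
#' @param lnc `GRanges` of lncRNA gene models (needs `gene_id`).
#' @param coding `GRanges` of protein-coding gene models (needs `gene_id`).
#' @param genicWindow genic distance cutoff in bp (default 5000).
#' @return data.frame with one row per lncRNA: `lnc_id`, `biotype`,
#'   `partner_id` (`NA` iff `IG`), `distance_bp` (0 if overlapping; gap to
#'   the nearest coding gene for `IG`, `NA` if the chromosome has none),
#'   `overlap_bp`, `five_prime_overlap` and `ambiguous_ends`.
#' @examples
#' genes <- readAnnotation(simulateAnnotation(
#'     list(geometrySpec("XH", overlap = 599),
#'          geometrySpec("IG", gap = 6000)), dir = tempdir())$paths["gtf"])
#' classifyBiotypes(genes[genes$gene_class == "lncRNA"],
#'                  genes[genes$gene_class == "protein_coding"])
#' @export
classifyBiotypes <- function(lnc, coding, genicWindow = 5000) {
    stopifnot(length(lnc) > 0)
    n <- length(lnc)
    out <- data.frame(
        lnc_id = lnc$gene_id,
        biotype = character(n), partner_id = NA_character_,
        distance_bp = NA_integer_, overlap_bp = 0L,
        five_prime_overlap = FALSE, ambiguous_ends = FALSE,
        stringsAsFactors = FALSE)
    nAmb <- 0L
    for (i in seq_len(n)) {
        li <- lnc[i]
        pid <- pairPartner(li, coding, genicWindow)
        if (is.na(pid)) {
            out$biotype[i] <- "IG"
            same <- coding[as.character(seqnames(coding)) ==
                           as.character(seqnames(li))]
            if (length(same)) {
                gaps <- pmax(pmax(start(same), start(li)) -
                             pmin(end(same), end(li)) - 1L, 0L)
                out$distance_bp[i] <- min(gaps)
            }
            next
        }
        ci <- coding[match(pid, coding$gene_id)]
        cl <- .classifyPair(start(li), end(li),
                            as.character(strand(li)),
                            start(ci), end(ci),
                            as.character(strand(ci)), genicWindow)
        out$biotype[i] <- cl$biotype
        out$partner_id[i] <- pid
        out$distance_bp[i] <- cl$distance
        out$overlap_bp[i] <- cl$overlap
        out$five_prime_overlap[i] <- cl$five_prime_overlap
        out$ambiguous_ends[i] <- cl$ambiguous
        if (cl$ambiguous) nAmb <- nAmb + 1L
    }
    if (nAmb) message(nAmb, " assignment(s) with ambiguous overlap ends")
    out
}

#' Write biotype assignments as TSV
#'
#' @param assignments output of [classifyBiotypes()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeBiotypeAssignments <- function(assignments, path) {
    writeTsv(assignments, path)
}
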