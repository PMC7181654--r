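#' Default corticogenesis timepoint labels
#'
#' The eight sampling days of the in vitro corticogenesis time course.
#'
#' @return character vector `D0, D7, D12, D19, D26, D49, D63, D77`.
#' @export
defaultTimepoints <- function() {
    c("D0", "D7", "D12", "D19", "D26", "D49", "D63", "D77")
}

#' Specify a coding/lncRNA pair geometry
#'
#' Describes one synthetic coding-gene/lncRNA pair realizing a positional
#' biotype. Exactly one of `gap` / `overlap` must be nonzero for the genic
#' labels that use them (`XH`, `XT`, `SD`, `SU`); containment labels
#' (`XI`, `XO`) derive their overlap from the gene lengths and take an
#' `inset` placing the inner gene; `IG` requires `gap > 5000`. Strands of
#' the lncRNA are implied: opposite for antisense labels, same for sense
#' labels, free (`strandLnc`) for `IG`.
#'
#' @param biotype one of [biotypeLabels()].
#' @param gap separation in bp when non-overlapping (>= 0).
#' @param overlap overlap in bp when overlapping (>= 0).
#' @param codingLen,lncLen gene-body lengths in bp (> 0).
#' @param strandCoding strand of the coding gene; the pair is mirrored for
#'   `"-"`, which preserves the biotype.
#' @param strandLnc lncRNA strand, only used for `IG`.
#' @param inset left offset of the inner gene for `XI`/`XO` (default:
#'   centered).
#' @return a `geometry_spec` list.
#' @examples
#' geometrySpec("XH", overlap = 599)  # divergent pair, 599 bp 5' overlap
#' @export
geometrySpec <- function(biotype, gap = 0, overlap = 0, codingLen = 2000,
                         lncLen = 1000, strandCoding = "+",
                         strandLnc = "+", inset = NULL) {
    stopifnot(biotype %in% biotypeLabels(), gap >= 0, overlap >= 0,
              codingLen > 0, lncLen > 0, strandCoding %in% c("+", "-"),
              strandLnc %in% c("+", "-"))
    if (biotype %in% c("XH", "XT")) {
        if ((gap > 0) == (overlap > 0))
            stop("exactly one of gap/overlap must be nonzero for ", biotype)
        if (overlap >= min(codingLen, lncLen))
            stop("partial overlap must be smaller than both genes")
        if (gap > 5000)
            stop("a gap above the 5 kb genic window cannot realize ", biotype)
    } else if (biotype == "XI") {
        if (gap > 0 || overlap > 0)
            stop("XI containment is set by the lengths, not gap/overlap")
        if (lncLen >= codingLen) stop("XI needs lncLen < codingLen")
        overlap <- lncLen
    } else if (biotype == "XO") {
        if (gap > 0 || overlap > 0)
            stop("XO containment is set by the lengths, not gap/overlap")
        if (lncLen <= codingLen) stop("XO needs lncLen > codingLen")
        overlap <- codingLen
    } else if (biotype %in% c("SD", "SU")) {
        if (overlap > 0 || gap == 0)
            stop(biotype, " needs a positive gap and no overlap")
        if (gap > 5000)
            stop("a gap above the 5 kb genic window cannot realize ", biotype)
    } else { # IG
        if (overlap > 0 || gap <= 5000)
            stop("IG needs gap > 5000 and no overlap")
    }
    structure(list(biotype = biotype, gap = as.integer(gap),
                   overlap = as.integer(overlap),
                   codingLen = as.integer(codingLen),
                   lncLen = as.integer(lncLen),
                   strandCoding = strandCoding, strandLnc = strandLnc,
                   inset = inset),
              class = "geometry_spec")
}

# local 0-based [start, end) coordinates of the lncRNA, coding at [0, Lc),
# coding on "+"; returns list(lstart, lend, lstrand)
.lncLocal <- function(sp) {
    Lc <- sp$codingLen; Ll <- sp$lncLen
    g <- sp$gap; o <- sp$overlap
    switch(sp$biotype,
        XH = if (o > 0) list(o - Ll, o, "-") else list(-g - Ll, -g, "-"),
        XT = if (o > 0) list(Lc - o, Lc - o + Ll, "-")
             else list(Lc + g, Lc + g + Ll, "-"),
        XI = { i <- if (is.null(sp$inset)) (Lc - Ll) %/% 2L else sp$inset
               stopifnot(i >= 0, i + Ll <= Lc)
               list(i, i + Ll, "-") },
        XO = { i <- if (is.null(sp$inset)) (Ll - Lc) %/% 2L else sp$inset
               stopifnot(i >= 0, Ll - i >= Lc)
               list(-i, -i + Ll, "-") },
        SD = list(Lc + g, Lc + g + Ll, "+"),
        SU = list(-g - Ll, -g, "+"),
        IG = list(Lc + g, Lc + g + Ll, sp$strandLnc))
}

#' Generate a synthetic annotation realizing requested geometries
#'
#' Lays the requested coding/lncRNA pairs left to right along a single
#' synthetic chromosome `chrS`, separated by 10-kb spacers so that no pair
#' interferes with its neighbours' genic windows, and emits a GTF
#' (gene/transcript/exon records with a `gene_biotype` attribute) plus a
#' truth table mapping every lncRNA to its planted biotype and partner.
#' Pairs whose spec has `strandCoding = "-"` are mirrored within their slot,
#' which preserves the biotype. The generator is deterministic: equal inputs
#' produce byte-identical files.
#'
#' @param specs list of [geometrySpec()] objects.
#' @param chromLen chromosome length in bp, or `NULL` to fit the specs; an
#'   explicit length too short for all pairs is an error.
#' @param spacer distance between consecutive pairs (default 10000,
#'   must exceed the 5-kb genic window).
#' @param dir if non-`NULL`, write `annotation.gtf` and `biotype_truth.tsv`
#'   there.
#' @param ids optional data.frame with `lnc_id`, `coding_id` per spec.
#' @return list with `genes` (gene-body `GRanges`), `truth` (data.frame
#'   `lnc_id`, `biotype`, `partner_id`), and `paths` (named character,
#'   when `dir` is given).
#' @export
simulateAnnotation <- function(specs, chromLen = NULL, spacer = 10000L,
                               dir = NULL, ids = NULL) {
    stopifnot(length(specs) > 0, spacer > 5000)
    n <- length(specs)
    if (is.null(ids))
        ids <- data.frame(lnc_id = sprintf("LNC%04d", seq_len(n)),
                          coding_id = sprintf("PC%04d", seq_len(n)))
    stopifnot(nrow(ids) == n, !anyDuplicated(c(ids$lnc_id, ids$coding_id)))
    rows <- vector("list", n)
    cursor <- as.integer(spacer)  # 0-based start of the first slot
    for (i in seq_len(n)) {
        sp <- specs[[i]]
        loc <- .lncLocal(sp)
        cs0 <- 0L; ce0 <- sp$codingLen
        ls0 <- loc[[1L]]; le0 <- loc[[2L]]
        lstr <- loc[[3L]]; cstr <- "+"
        lo <- min(cs0, ls0); hi <- max(ce0, le0)
        if (sp$strandCoding == "-") {
            refl <- function(s, e) c(lo + hi - e, lo + hi - s)
            cr <- refl(cs0, ce0); lr <- refl(ls0, le0)
            cs0 <- cr[1L]; ce0 <- cr[2L]; ls0 <- lr[1L]; le0 <- lr[2L]
            cstr <- "-"; lstr <- if (lstr == "+") "-" else "+"
        }
        shift <- cursor - lo
        rows[[i]] <- data.frame(
            gene_id = c(ids$coding_id[i], ids$lnc_id[i]),
            start = c(cs0, ls0) + shift + 1L,   # 1-based inclusive
            end = c(ce0, le0) + shift,
            strand = c(cstr, lstr),
            gene_biotype = c("protein_coding", "lncRNA"),
            stringsAsFactors = FALSE)
        cursor <- cursor + (hi - lo) + as.integer(spacer)
    }
    tab <- do.call(rbind, rows)
    needed <- cursor
    if (!is.null(chromLen) && chromLen < needed)
        stop("chromosome too short: need ", needed, " bp for all pairs")
    truth <- data.frame(
        lnc_id = ids$lnc_id,
        biotype = vapply(specs, `[[`, character(1), "biotype"),
        partner_id = ifelse(vapply(specs, `[[`, character(1),
                                   "biotype") == "IG",
                            NA_character_, ids$coding_id),
        stringsAsFactors = FALSE)
    genes <- GRanges("chrS", IRanges(tab$start, tab$end),
                     strand = tab$strand)
    mcols(genes) <- DataFrame(gene_id = tab$gene_id,
                              gene_class = ifelse(
                                  tab$gene_biotype == "lncRNA",
                                  "lncRNA", "protein_coding"),
                              n_exons = 1L)
    names(genes) <- tab$gene_id
    paths <- character(0)
    if (!is.null(dir)) {
        dir.create(dir, recursive = TRUE, showWarnings = FALSE)
        feat <- rep(genes, each = 3L)
        mcols(feat) <- NULL
        feat$source <- "lncTempo"
        feat$type <- rep(c("gene", "transcript", "exon"), length(genes))
        feat$gene_id <- rep(tab$gene_id, each = 3L)
        feat$transcript_id <- ifelse(feat$type == "gene", NA_character_,
                                     paste0(feat$gene_id, ".t1"))
        feat$gene_biotype <- rep(tab$gene_biotype, each = 3L)
        gtf <- file.path(dir, "annotation.gtf")
        rtracklayer::export(feat, gtf, format = "gtf")
        tru <- file.path(dir, "biotype_truth.tsv")
        writeTsv(truth, tru)
        paths <- c(gtf = gtf, truth = tru)
    }
    list(genes = genes, truth = truth, paths = paths)
}

#' Specify a planted temporal cluster
#'
#' @param stage stage label (`pluripotency`, `commitment`, `later`, ...).
#' @param genes character vector of gene ids planted in this cluster
#'   (marker genes included here are thereby forced into the cluster).
#' @param profile mean log-RPKM trajectory (natural log), one value per
#'   timepoint.
#' @param noiseSd per-cell lognormal noise SD (>= 0).
#' @return a `planted_cluster` list.
#' @export
plantedCluster <- function(stage, genes, profile, noiseSd = 0.25) {
    stopifnot(length(genes) > 0, noiseSd >= 0, is.numeric(profile))
    structure(list(stage = stage, genes = genes, profile = profile,
                   noiseSd = noiseSd),
              class = "planted_cluster")
}

#' Generate a temporal RPKM matrix with planted stage clusters
#'
#' Builds a gene x timepoint RPKM matrix under a log-normal model
#' `rpkm = exp(profile + N(0, noiseSd))` (strictly positive and heavy-tailed
#' like real RPKM). Genes named by the planted clusters follow their
#' cluster's trajectory; all other supplied genes are background with a flat
#' low-mean profile (below the 1-RPKM expressed cutoff by default). A gene
#' may belong to at most one cluster; duplicated gene ids are an error.
#'
#' @param geneIds all gene ids to emit (cluster genes not listed here are
#'   added automatically).
#' @param clusters list of [plantedCluster()] objects.
#' @param timepoints timepoint labels (default [defaultTimepoints()]).
#' @param bgLogMean background log-RPKM mean (default `log(0.4)`).
#' @param bgNoiseSd background noise SD (default 0.1).
#' @param seed integer seed.
#' @param path optional TSV output file.
#' @return list with `rpkm` (matrix), `truth` (data.frame `gene_id`,
#'   `cluster`, `stage`) and `path`.
#' @export
simulateExpression <- function(geneIds, clusters,
                               timepoints = defaultTimepoints(),
                               bgLogMean = log(0.4), bgNoiseSd = 0.1,
                               seed = 1L, path = NULL) {
    clGenes <- unlist(lapply(clusters, `[[`, "genes"))
    if (anyDuplicated(clGenes))
        stop("a gene is planted in more than one cluster")
    if (anyDuplicated(geneIds)) stop("duplicate gene ids")
    geneIds <- union(geneIds, clGenes)
    for (cl in clusters)
        if (length(cl$profile) != length(timepoints))
            stop("profile length must equal the number of timepoints")
    Tn <- length(timepoints)
    m <- withSeed(seed, {
        out <- matrix(exp(bgLogMean +
                          stats::rnorm(length(geneIds) * Tn, 0, bgNoiseSd)),
                      length(geneIds), Tn,
                      dimnames = list(geneIds, timepoints))
        for (cl in clusters) {
            noise <- matrix(stats::rnorm(length(cl$genes) * Tn, 0,
                                         cl$noiseSd),
                            length(cl$genes), Tn)
            out[cl$genes, ] <- exp(sweep(noise, 2, cl$profile, `+`))
        }
        out
    })
    truth <- data.frame(gene_id = geneIds, cluster = "background",
                        stage = NA_character_, stringsAsFactors = FALSE)
    for (j in seq_along(clusters)) {
        hit <- truth$gene_id %in% clusters[[j]]$genes
        truth$cluster[hit] <- paste0("planted", j)
        truth$stage[hit] <- clusters[[j]]$stage
    }
    if (!is.null(path)) writeMatrixTsv(m, path)
    list(rpkm = m, truth = truth, path = path)
}

#' Generate replicate-rich samples with a planted dependency topology
#'
#' Draws `nSamples` i.i.d. multivariate Gaussian samples over `nNodes`
#' genes under one of three topologies: `hub` (one node correlated with
#' every spoke at `edgeStrength`, spokes conditionally independent given the
#' hub), `chain` (a first-order Markov chain, so the data-processing
#' inequality applies to non-adjacent nodes), or `independent`. MI
#' estimation needs replicates, so network fixtures require `nSamples >= 30`.
#'
#' @param topology `"hub"`, `"chain"` or `"independent"`.
#' @param nNodes number of genes (hub topology: 1 hub + `nNodes - 1` spokes).
#' @param nSamples number of samples (>= 30).
#' @param edgeStrength pairwise correlation of a direct edge, in (0, 1).
#' @param seed integer seed.
#' @param geneIds optional gene names (default `G1..Gn`; hub first).
#' @return list with `data` (samples x genes matrix) and `edges` (truth
#'   edge data.frame `gene_i`, `gene_j`, canonical order).
#' @export
simulateNetworkSamples <- function(topology = c("hub", "chain",
                                                "independent"),
                                   nNodes, nSamples, edgeStrength = 0.8,
                                   seed = 1L, geneIds = NULL) {
    topology <- match.arg(topology)
    stopifnot(nNodes >= 2, edgeStrength > 0, edgeStrength < 1)
    if (nSamples < 30)
        stop("network fixtures need at least 30 samples")
    if (is.null(geneIds)) geneIds <- paste0("G", seq_len(nNodes))
    stopifnot(length(geneIds) == nNodes)
    r <- edgeStrength
    m <- withSeed(seed, {
        out <- matrix(stats::rnorm(nSamples * nNodes), nSamples, nNodes)
        if (topology == "hub") {
            for (j in seq_len(nNodes - 1L) + 1L)
                out[, j] <- r * out[, 1L] + sqrt(1 - r^2) * out[, j]
        } else if (topology == "chain") {
            for (j in seq_len(nNodes - 1L) + 1L)
                out[, j] <- r * out[, j - 1L] + sqrt(1 - r^2) * out[, j]
        }
        out
    })
    colnames(m) <- geneIds
    edges <- switch(topology,
        hub = data.frame(gene_i = geneIds[1L],
                         gene_j = geneIds[-1L], stringsAsFactors = FALSE),
        chain = data.frame(gene_i = geneIds[-nNodes],
                           gene_j = geneIds[-1L], stringsAsFactors = FALSE),
        independent = data.frame(gene_i = character(),
                                 gene_j = character(),
                                 stringsAsFactors = FALSE))
    if (nrow(edges)) {
        swap <- edges$gene_i > edges$gene_j
        tmp <- edges$gene_i[swap]
        edges$gene_i[swap] <- edges$gene_j[swap]
        edges$gene_j[swap] <- tmp
        edges <- edges[order(edges$gene_i, edges$gene_j), , drop = FALSE]
        rownames(edges) <- NULL
    }
    list(data = m, edges = edges)
}

# a fixed, strongly non-uniform codon usage table (stop codons excluded);
# compositional asymmetry is what the Fickett statistic detects
.codonWeights <- function() {
    codons <- as.vector(outer(outer(c("T", "C", "A", "G"),
                                    c("T", "C", "A", "G"), paste0),
                              c("T", "C", "A", "G"), paste0))
    codons <- setdiff(codons, c("TAA", "TAG", "TGA"))
    w <- rep(1, length(codons))
    names(w) <- codons
    favored <- c(GCC = 12, GAG = 12, AAG = 10, CTG = 14, GAC = 8, GCT = 6,
                 AAC = 6, ATC = 8, GGC = 8, CAG = 10, TTC = 6, ACC = 6,
                 GTG = 8, TCC = 5, CCC = 5, GAT = 5, TAC = 4, ATG = 4)
    w[names(favored)] <- favored
    w / sum(w)
}

#' Generate coding and noncoding transcript sequences
#'
#' Coding sequences carry a planted long ORF (default 80% of the length):
#' `ATG`, codons drawn from a fixed non-uniform usage table (no in-frame
#' stops), and a stop codon, flanked by uniform-random UTRs. Noncoding
#' sequences are uniform-random nucleotides (`method = "uniform"`) or
#' composition-preserving shuffles of coding sequences
#' (`method = "shuffle"`), which destroy codon-position structure while
#' keeping base content.
#'
#' @param nCoding,nNoncoding sequence counts (>= 0).
#' @param lengthBp sequence length (>= 200).
#' @param orfFraction planted ORF length as a fraction of `lengthBp`
#'   (default 0.8; must be >= 0.6 so the ORF dominates the transcript).
#' @param method noncoding construction (see above).
#' @param seed integer seed.
#' @param path optional FASTA output file.
#' @return list with `seqs` ([Biostrings::DNAStringSet]), `labels`
#'   (data.frame `transcript_id`, `class`) and `path`.
#' @export
simulateSequences <- function(nCoding, nNoncoding, lengthBp = 1200L,
                              orfFraction = 0.8,
                              method = c("uniform", "shuffle"),
                              seed = 1L, path = NULL) {
    method <- match.arg(method)
    stopifnot(nCoding >= 0, nNoncoding >= 0, orfFraction >= 0.6,
              orfFraction <= 1)
    if (lengthBp < 200L) stop("sequences must be at least 200 bp")
    bases <- c("A", "C", "G", "T")
    cw <- .codonWeights()
    out <- withSeed(seed, {
        mkCoding <- function() {
            nCod <- max(3L, floor(lengthBp * orfFraction / 3))
            inner <- sample(names(cw), nCod - 2L, replace = TRUE, prob = cw)
            orf <- paste0("ATG", paste(inner, collapse = ""), "TAA")
            rest <- lengthBp - nchar(orf)
            u5 <- rest %/% 2L; u3 <- rest - u5
            paste0(paste(sample(bases, u5, TRUE), collapse = ""), orf,
                   paste(sample(bases, u3, TRUE), collapse = ""))
        }
        coding <- vapply(seq_len(nCoding), function(i) mkCoding(),
                         character(1))
        mkNoncoding <- function(i) {
            if (method == "uniform" || !length(coding))
                paste(sample(bases, lengthBp, TRUE), collapse = "")
            else { # composition-preserving shuffle of a coding sequence
                src <- strsplit(coding[(i - 1L) %% length(coding) + 1L],
                                "")[[1L]]
                paste(src[sample.int(length(src))], collapse = "")
            }
        }
        noncoding <- vapply(seq_len(nNoncoding), mkNoncoding, character(1))
        list(coding = coding, noncoding = noncoding)
    })
    ids <- c(sprintf("TX_C%03d", seq_len(nCoding)),
             sprintf("TX_N%03d", seq_len(nNoncoding)))
    seqs <- Biostrings::DNAStringSet(c(out$coding, out$noncoding))
    names(seqs) <- ids
    labels <- data.frame(
        transcript_id = ids,
        class = rep(c("coding", "noncoding"), c(nCoding, nNoncoding)),
        stringsAsFactors = FALSE)
    if (!is.null(path)) Biostrings::writeXStringSet(seqs, path)
    list(seqs = seqs, labels = labels, path = path)
}
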