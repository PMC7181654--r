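# Independent oracles, written as straight-line re-derivations that share no
# code with the package implementation.

## ---- biotype rule-table oracle ------------------------------------------
# Gene records are plain lists: list(start=, end=, strand=) with 1-based
# inclusive coordinates. Overlap is computed by per-base set intersection.

oracleOverlap <- function(a, b) {
    length(intersect(seq(a$start, a$end), seq(b$start, b$end)))
}

oracleGap <- function(a, b) {
    if (oracleOverlap(a, b) > 0) return(0L)
    max(a$start, b$start) - min(a$end, b$end) - 1L
}

oracleFivePrime <- function(g) if (g$strand == "+") g$start else g$end

oracleThreePrime <- function(g) if (g$strand == "+") g$end else g$start

# partner choice: max per-base overlap, then min gap within window, ties by id
oraclePartner <- function(lnc, codingList, window = 5000) {
    ov <- vapply(codingList, oracleOverlap, numeric(1), a = lnc)
    ids <- vapply(codingList, `[[`, character(1), "id")
    if (any(ov > 0)) {
        cand <- ids[ov == max(ov)]
        return(sort(cand)[1])
    }
    gaps <- vapply(codingList, oracleGap, numeric(1), a = lnc)
    ok <- gaps <= window
    if (!any(ok)) return(NA_character_)
    cand <- ids[ok][gaps[ok] == min(gaps[ok])]
    sort(cand)[1]
}

oracleBiotype <- function(lnc, codingList, window = 5000) {
    pid <- oraclePartner(lnc, codingList, window)
    if (is.na(pid)) return("IG")
    cg <- codingList[[which(vapply(codingList, `[[`, character(1),
                                   "id") == pid)]]
    lncBases <- seq(lnc$start, lnc$end)
    cBases <- seq(cg$start, cg$end)
    ovBases <- intersect(lncBases, cBases)
    if (length(ovBases) > 0) {
        if (lnc$strand == cg$strand) return("unclassified_sense_overlap")
        if (all(lncBases %in% cBases)) return("XI")
        if (all(cBases %in% lncBases)) return("XO")
        l5in <- oracleFivePrime(lnc) %in% ovBases
        c5in <- oracleFivePrime(cg) %in% ovBases
        if (l5in && c5in) return("XH")
        if (!l5in && !c5in) return("XT")
        return(if (l5in) "XH" else "XT")
    }
    gap <- oracleGap(lnc, cg)
    if (gap > window) return("IG")
    if (lnc$strand == cg$strand) {
        c3 <- oracleThreePrime(cg)
        downstream <- if (cg$strand == "+") lnc$start > c3
                      else lnc$end < c3
        return(if (downstream) "SD" else "SU")
    }
    # antisense non-overlapping: which ends face each other across the gap?
    lncLeft <- lnc$end < cg$start
    lncFacing <- if (lncLeft) lnc$end else lnc$start
    cFacing <- if (lncLeft) cg$start else cg$end
    lncFacingIs5 <- lncFacing == oracleFivePrime(lnc)
    cFacingIs5 <- cFacing == oracleFivePrime(cg)
    if (lncFacingIs5 && cFacingIs5) "XH" else "XT"
}

# GRanges of parsed gene models -> the oracle's plain-list records
asOracleRecords <- function(gr) {
    lapply(seq_along(gr), function(i) list(
        id = gr$gene_id[i],
        start = GenomicRanges::start(gr)[i],
        end = GenomicRanges::end(gr)[i],
        strand = as.character(GenomicRanges::strand(gr)[i])))
}

# the exhaustive geometry grid: every placeable biotype/overlap/gap/strand/
# length combination (>= 500 cases)
biotypeGrid <- function() {
    lens <- list(c(2000, 1000), c(3000, 800), c(1500, 700),
                 c(2500, 1200), c(4000, 900), c(1200, 600))
    overlaps <- c(1, 5, 50, 100, 299, 599)
    gaps <- c(1, 100, 1000, 2500, 4999, 5000)
    igGaps <- c(5001, 5500, 8000, 10000)
    strands <- c("+", "-")
    specs <- list(); labels <- character()
    add <- function(sp, bt) {
        specs[[length(specs) + 1L]] <<- sp
        labels[length(labels) + 1L] <<- bt
    }
    for (ln in lens) for (st in strands) {
        for (o in overlaps[overlaps < min(ln)]) {
            add(geometrySpec("XH", overlap = o, codingLen = ln[1],
                             lncLen = ln[2], strandCoding = st), "XH")
            add(geometrySpec("XT", overlap = o, codingLen = ln[1],
                             lncLen = ln[2], strandCoding = st), "XT")
        }
        for (g in gaps) {
            add(geometrySpec("XH", gap = g, codingLen = ln[1],
                             lncLen = ln[2], strandCoding = st), "XH")
            add(geometrySpec("XT", gap = g, codingLen = ln[1],
                             lncLen = ln[2], strandCoding = st), "XT")
            add(geometrySpec("SD", gap = g, codingLen = ln[1],
                             lncLen = ln[2], strandCoding = st), "SD")
            add(geometrySpec("SU", gap = g, codingLen = ln[1],
                             lncLen = ln[2], strandCoding = st), "SU")
        }
        for (inset in c(0, 17, 200)) {
            add(geometrySpec("XI", codingLen = ln[1], lncLen = ln[2],
                             strandCoding = st, inset = inset), "XI")
            add(geometrySpec("XO", codingLen = ln[2], lncLen = ln[1],
                             strandCoding = st, inset = inset), "XO")
        }
        for (g in igGaps)
            add(geometrySpec("IG", gap = g, codingLen = ln[1],
                             lncLen = ln[2], strandCoding = st,
                             strandLnc = if (g %% 2) "+" else "-"), "IG")
    }
    list(specs = specs, labels = labels)
}

## ---- textbook fuzzy c-means ---------------------------------------------
# plain-loop implementation of the two update equations
fcmOracle <- function(x, init, m = 1.25, tol = 1e-6, maxIter = 1000) {
    cen <- init
    nG <- nrow(x); nC <- nrow(cen)
    u <- matrix(0, nG, nC)
    for (it in seq_len(maxIter)) {
        for (i in seq_len(nG)) {
            d <- numeric(nC)
            for (j in seq_len(nC))
                d[j] <- sqrt(sum((x[i, ] - cen[j, ])^2))
            if (any(d == 0)) {
                u[i, ] <- as.numeric(d == 0) / sum(d == 0)
            } else {
                for (j in seq_len(nC)) {
                    s <- 0
                    for (k in seq_len(nC))
                        s <- s + (d[j] / d[k])^(2 / (m - 1))
                    u[i, j] <- 1 / s
                }
            }
        }
        newCen <- cen
        for (j in seq_len(nC)) {
            num <- rep(0, ncol(x)); den <- 0
            for (i in seq_len(nG)) {
                w <- u[i, j]^m
                num <- num + w * x[i, ]
                den <- den + w
            }
            newCen[j, ] <- num / den
        }
        shift <- max(abs(newCen - cen))
        cen <- newCen
        if (shift < tol) break
    }
    list(memberships = u, centroids = cen, iterations = it)
}

## ---- O(n^3) TOM -----------------------------------------------------------
tomOracle <- function(a) {
    n <- nrow(a)
    A <- a; diag(A) <- 0
    tom <- diag(n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
        if (i == j) next
        num <- A[i, j]
        for (u in seq_len(n)) num <- num + A[i, u] * A[u, j]
        ki <- sum(A[i, ]); kj <- sum(A[j, ])
        tom[i, j] <- num / (min(ki, kj) + 1 - A[i, j])
    }
    tom
}

## ---- ORF scanner (stop-indexed, a different algorithm) --------------------
orfOracle <- function(seq) {
    s <- toupper(seq)
    best <- 0L
    for (f in 0:2) {
        ncod <- (nchar(s) - f) %/% 3
        if (ncod < 1) next
        codons <- substring(s, f + 1 + 3 * (seq_len(ncod) - 1),
                            f + 3 * seq_len(ncod))
        stops <- which(codons %in% c("TAA", "TAG", "TGA"))
        atgs <- which(codons == "ATG")
        prev <- 0L
        for (st in stops) {
            cand <- atgs[atgs > prev & atgs <= st]
            if (length(cand))
                best <- max(best, (st - min(cand) + 1L) * 3L)
            prev <- st
        }
    }
    list(coverage = best / nchar(s), longest_orf_bp = best)
}

## ---- misc -----------------------------------------------------------------
adjustedRand <- function(a, b) mclust::adjustedRandIndex(a, b)

randomDnaString <- function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# build an MINetwork object directly (for DPI / ranking unit tests)
makeNet <- function(edges, nodes = NULL, threshold = 0) {
    swap <- edges$gene_i > edges$gene_j
    tmp <- edges$gene_i[swap]
    edges$gene_i[swap] <- edges$gene_j[swap]
    edges$gene_j[swap] <- tmp
    edges <- edges[order(edges$gene_i, edges$gene_j), , drop = FALSE]
    rownames(edges) <- NULL
    if (is.null(nodes)) nodes <- sort(unique(c(edges$gene_i, edges$gene_j)))
    methods::new("MINetwork", nodes = nodes, edges = edges,
                 threshold = threshold, dpiTolerance = NA_real_)
}
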