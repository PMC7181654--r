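# equal-frequency binning: deterministic, ties broken by position
.equalFreqBin <- function(v, B) {
    r <- rank(v, ties.method = "first")
    as.integer(ceiling(r * B / length(v)))
}

# plug-in MI in bits from two integer bin vectors on 1..B
.miFromBins <- function(bx, by, B) {
    n <- length(bx)
    joint <- tabulate(bx + B * (by - 1L), nbins = B * B) / n
    px <- tabulate(bx, nbins = B) / n
    py <- tabulate(by, nbins = B) / n
    pp <- outer(px, py)
    dim(joint) <- c(B, B)
    nz <- joint > 0
    sum(joint[nz] * log2(joint[nz] / pp[nz]))
}

#' Plug-in mutual information with equal-frequency binning
#'
#' Discretizes both vectors into `B` equal-frequency bins (ranks with
#' deterministic tie-breaking) and returns the plug-in mutual information
#' `sum p(a,b) log2(p(a,b) / (p(a) p(b)))` in bits. With `bins = "auto"`,
#' `B = floor(sqrt(n))`. `MI(x, x) = log2(B)` exactly whenever `n` is a
#' multiple of `B` (the binned variable is uniform by construction), and the
#' estimator is exactly symmetric in its arguments.
#'
#' The plug-in estimate is biased upward by roughly
#' `(B - 1)^2 / (2 n ln 2)` bits for independent inputs; see the vignette.
#' [inferNetwork()] absorbs this bias through its permutation null. A
#' constant vector yields MI 0 with a warning.
#'
#' @param x,y numeric vectors of equal length (>= 8), finite values.
#' @param bins integer number of bins, or `"auto"`.
#' @return mutual information in bits (>= 0).
#' @examples
#' x <- rnorm(1024)
#' mutualInformation(x, x, bins = 32)  # log2(32) = 5
#' @export
mutualInformation <- function(x, y, bins = "auto") {
    if (length(x) != length(y)) stop("length mismatch")
    n <- length(x)
    if (n < 8L) stop("need at least 8 paired samples")
    if (any(!is.finite(x)) || any(!is.finite(y)))
        stop("non-finite values")
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
        warning("constant vector: MI is 0")
        return(0)
    }
    B <- if (identical(bins, "auto")) max(2L, floor(sqrt(n)))
         else as.integer(bins)
    if (B < 2L) stop("need at least 2 bins")
    .miFromBins(.equalFreqBin(x, B), .equalFreqBin(y, B), B)
}

#' Infer a mutual-information gene network
#'
#' Estimates MI for every gene pair and keeps edges whose MI reaches the
#' `(1 - alpha)` quantile of a pooled permutation null: for each of `nPerm`
#' draws, a random gene pair is taken and one member's samples are shuffled
#' before re-estimating MI. Because the null is built with the same binned
#' plug-in estimator, its finite-sample bias cancels out of the thresholding
#' decision. With `alpha = 1` the threshold sits at the null minimum and the
#' graph is (essentially) complete.
#'
#' @param data samples x genes numeric matrix with column names; at least 3
#'   genes, and >= 30 samples recommended (a warning is raised below that).
#' @param alpha permutation p-value cutoff (default 0.05).
#' @param nPerm permutation draws for the pooled null (default 200).
#' @param bins see [mutualInformation()].
#' @param seed integer seed for the permutation null.
#' @return an [MINetwork-class] (DPI not yet applied).
#' @export
inferNetwork <- function(data, alpha = 0.05, nPerm = 200L, bins = "auto",
                         seed = 1L) {
    stopifnot(is.matrix(data), !is.null(colnames(data)))
    p <- ncol(data); n <- nrow(data)
    if (p < 3L) stop("need at least 3 genes")
    if (n < 30L) warning("fewer than 30 samples: MI estimates are unstable")
    B <- if (identical(bins, "auto")) max(2L, floor(sqrt(n)))
         else as.integer(bins)
    binned <- apply(data, 2, .equalFreqBin, B = B)
    genes <- colnames(data)
    pairs <- utils::combn(p, 2L)
    mi <- vapply(seq_len(ncol(pairs)), function(k)
        .miFromBins(binned[, pairs[1L, k]], binned[, pairs[2L, k]], B),
        numeric(1))
    null <- withSeed(seed, {
        vapply(seq_len(nPerm), function(b) {
            ij <- sample.int(p, 2L)
            .miFromBins(binned[, ij[1L]],
                        binned[sample.int(n), ij[2L]], B)
        }, numeric(1))
    })
    threshold <- as.numeric(stats::quantile(null, 1 - alpha, names = FALSE))
    keep <- mi >= threshold
    gi <- genes[pairs[1L, keep]]
    gj <- genes[pairs[2L, keep]]
    swap <- gi > gj
    tmp <- gi[swap]; gi[swap] <- gj[swap]; gj[swap] <- tmp
    ord <- order(gi, gj)
    edges <- data.frame(gene_i = gi[ord], gene_j = gj[ord],
                        mi = mi[keep][ord], stringsAsFactors = FALSE)
    methods::new("MINetwork", nodes = genes, edges = edges,
                 threshold = threshold, dpiTolerance = NA_real_)
}

#' Prune indirect edges with the data-processing inequality
#'
#' For every triangle (i, j, k), the edge with the smallest MI is marked for
#' removal if its MI is below `(1 - tolerance)` times the smaller of the
#' other two; all marks are collected against the unpruned network (the
#' classic one-pass scheme), then removed together. Two guarantees hold on
#' the output: a triangle whose two weakest edges tie loses no edge, and an
#' edge that is the maximum of any triangle is never removed (an edge marked
#' as weakest in one triangle but maximal in another is kept). Edges are
#' scanned in canonical sorted order, so pruning is deterministic.
#'
#' @param net an [MINetwork-class].
#' @param tolerance DPI tolerance in `[0, 1]` (default 0.15).
#' @return the pruned [MINetwork-class].
#' @export
applyDPI <- function(net, tolerance = 0.15) {
    stopifnot(methods::is(net, "MINetwork"),
              tolerance >= 0, tolerance <= 1)
    e <- edgeTable(net)
    if (nrow(e) < 3L) {
        net@dpiTolerance <- tolerance
        return(net)
    }
    key <- paste(e$gene_i, e$gene_j, sep = "\r")
    miOf <- structure(e$mi, names = key)
    nbr <- split(c(e$gene_j, e$gene_i), c(e$gene_i, e$gene_j))
    pkey <- function(a, b) ifelse(a < b, paste(a, b, sep = "\r"),
                                  paste(b, a, sep = "\r"))
    drop <- character(0)
    keepMax <- character(0)
    for (r in seq_len(nrow(e))) {
        i <- e$gene_i[r]; j <- e$gene_j[r]
        common <- intersect(nbr[[i]], nbr[[j]])
        common <- common[common > j]  # each triangle visited once
        for (k in common) {
            trio <- c(pkey(i, j), pkey(i, k), pkey(j, k))
            vals <- miOf[trio]
            o <- order(vals)
            keepMax <- c(keepMax, trio[vals >= max(vals)])
            if (vals[o[1L]] < vals[o[2L]] &&
                vals[o[1L]] < (1 - tolerance) * vals[o[2L]])
                drop <- c(drop, trio[o[1L]])
        }
    }
    drop <- setdiff(drop, keepMax)
    if (length(drop)) e <- e[!(key %in% drop), , drop = FALSE]
    rownames(e) <- NULL
    methods::new("MINetwork", nodes = net@nodes, edges = e,
                 threshold = net@threshold, dpiTolerance = tolerance)
}

# degree and summed MI per node that has at least one edge
.nodeStats <- function(net) {
    e <- edgeTable(net)
    if (!nrow(e))
        return(data.frame(gene = character(), degree = integer(),
                          mi_sum = numeric()))
    g <- c(e$gene_i, e$gene_j)
    m <- c(e$mi, e$mi)
    deg <- tapply(m, g, length)
    msum <- tapply(m, g, sum)
    data.frame(gene = names(deg), degree = as.integer(deg),
               mi_sum = as.numeric(msum), row.names = NULL,
               stringsAsFactors = FALSE)
}

#' Rank genes by network degree (hub identification)
#'
#' Nodes with at least one edge, sorted by decreasing degree; ties broken by
#' decreasing summed edge MI, then by gene id. The top entry is the network
#' hub.
#'
#' @param net an [MINetwork-class].
#' @return data.frame `gene`, `degree`, `mi_sum`, best first (empty for an
#'   edgeless network).
#' @export
hubRank <- function(net) {
    st <- .nodeStats(net)
    st[order(-st$degree, -st$mi_sum, st$gene), , drop = FALSE]
}

#' Count multiedge partners within a gene set
#'
#' The network-change statistic: the number of genes in `geneSet` with
#' degree >= 2 in the network ("partner of multiedge node pairs").
#'
#' @param net an [MINetwork-class].
#' @param geneSet character vector of gene ids (nonempty).
#' @return integer count.
#' @export
multiedgePartnerCount <- function(net, geneSet) {
    stopifnot(length(geneSet) > 0)
    st <- .nodeStats(net)
    sum(st$degree >= 2L & st$gene %in% geneSet)
}

#' Network change between two conditions
#'
#' [multiedgePartnerCount()] per gene set in each network and the signed
#' difference, e.g. between the pluripotency (day 0) and neuronal
#' commitment (day 7) networks per biotype.
#'
#' @param net0,net1 [MINetwork-class] objects on comparable node universes.
#' @param sets named list biotype -> gene ids.
#' @return data.frame `biotype`, `count_t0`, `count_t1`, `change`.
#' @export
networkDelta <- function(net0, net1, sets) {
    stopifnot(length(sets) > 0, !is.null(names(sets)))
    c0 <- vapply(sets, multiedgePartnerCount, integer(1), net = net0)
    c1 <- vapply(sets, multiedgePartnerCount, integer(1), net = net1)
    data.frame(biotype = names(sets), count_t0 = as.integer(c0),
               count_t1 = as.integer(c1),
               change = as.integer(c1 - c0), row.names = NULL,
               stringsAsFactors = FALSE)
}
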