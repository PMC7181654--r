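# R^2 of the log-log linear fit of the degree distribution of k
.scaleFreeFitR2 <- function(k, nBreaks = 10) {
    if (max(k) - min(k) < 1e-12) return(0)
    cuts <- cut(k, breaks = nBreaks)
    p <- tapply(k, cuts, length)
    km <- tapply(k, cuts, mean)
    ok <- !is.na(p) & !is.na(km) & km > 0
    p <- p[ok] / sum(p[ok]); km <- km[ok]
    if (length(p) < 3L) return(0)
    fit <- stats::lm(log10(p) ~ log10(km))
    r2 <- summary(fit)$r.squared
    if (stats::coef(fit)[2] > 0) 0 else r2  # scale-free means decreasing
}

#' Select the soft-threshold power
#'
#' Evaluates, for each candidate power beta, the unsigned adjacency
#' `|cor|^beta` and the R^2 of a linear fit of `log10 p(k)` against
#' `log10 k` (k = weighted connectivity, binned). Returns the smallest power
#' reaching `targetR2`; if none does, the power with the best fit, with a
#' warning. Raising beta weakly decreases every off-diagonal adjacency
#' entry, so the fit generally improves and then saturates.
#'
#' @param corr symmetric gene x gene Pearson correlation matrix.
#' @param candidates integer powers to try (default 1:20).
#' @param targetR2 scale-free fit target (default 0.8).
#' @param nBreaks connectivity bins for the fit (default 10).
#' @return list with `power` (the selected beta) and `fit` (data.frame of
#'   `power`, `r2`).
#' @export
selectSoftPower <- function(corr, candidates = 1:20, targetR2 = 0.8,
                            nBreaks = 10) {
    stopifnot(is.matrix(corr), nrow(corr) == ncol(corr))
    if (nrow(corr) < 20L)
        stop("scale-free fit needs at least 20 genes")
    if (max(abs(corr - t(corr))) > 1e-8) stop("correlation must be symmetric")
    r2 <- vapply(candidates, function(b) {
        a <- abs(corr)^b
        diag(a) <- 0
        .scaleFreeFitR2(rowSums(a), nBreaks)
    }, numeric(1))
    fit <- data.frame(power = candidates, r2 = r2)
    ok <- which(r2 >= targetR2)
    if (length(ok)) power <- candidates[ok[1L]]
    else {
        warning("no candidate power reaches the scale-free fit target; ",
                "using the best fit")
        power <- candidates[which.max(r2)]
    }
    list(power = power, fit = fit)
}

#' Unsigned adjacency from correlations
#'
#' `a_ij = |cor_ij|^beta` (unsigned, the default) or
#' `((1 + cor_ij)/2)^beta` (signed variant). Unit diagonal.
#'
#' @param corr symmetric correlation matrix.
#' @param beta soft-threshold power.
#' @param signed use the signed transform (default FALSE).
#' @return adjacency matrix in `[0, 1]`.
#' @export
adjacencyFromCorr <- function(corr, beta, signed = FALSE) {
    a <- if (signed) ((1 + corr) / 2)^beta else abs(corr)^beta
    diag(a) <- 1
    a
}

#' Topological overlap matrix
#'
#' Converts an adjacency matrix into the (unsigned) topological overlap
#' matrix: for `i != j`,
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `k = rowSums(a)` over off-diagonal entries, and `TOM_ii = 1`. Values lie
#' in `[0, 1]`; two nodes connected only to each other with `a = 1` have
#' `TOM = 1`, and an edgeless adjacency gives all-zero off-diagonal TOM.
#'
#' @param a symmetric adjacency matrix with entries in `[0, 1]` (the
#'   diagonal is ignored).
#' @return the TOM, same dimensions and dimnames as `a`.
#' @export
tomFromAdjacency <- function(a) {
    stopifnot(is.matrix(a), nrow(a) == ncol(a))
    if (max(abs(a - t(a))) > 1e-8) stop("adjacency must be symmetric")
    A <- a
    diag(A) <- 0
    L <- A %*% A
    k <- rowSums(A)
    kmin <- outer(k, k, pmin)
    tom <- (L + A) / (kmin + 1 - A)
    diag(tom) <- 1
    dimnames(tom) <- dimnames(a)
    tom
}

#' Detect co-expression modules from a TOM
#'
#' Average-linkage hierarchical clustering on the dissimilarity `1 - TOM`,
#' cut statically at `cutHeight`; clusters smaller than `minModuleSize` are
#' relabelled 0 (unassigned/grey). Remaining modules get contiguous integer
#' labels ordered by decreasing size (ties by the lexicographically smallest
#' member gene), so both the partition and the labels themselves are
#' reproducible and invariant to gene ordering.
#'
#' @param tom topological overlap matrix (see [tomFromAdjacency()]).
#' @param cutHeight static tree-cut height on `1 - TOM` (default 0.99).
#' @param minModuleSize minimum genes per module (default 10).
#' @return named integer vector of module labels (0 = unassigned).
#' @export
detectModules <- function(tom, cutHeight = 0.99, minModuleSize = 10) {
    stopifnot(is.matrix(tom), nrow(tom) == ncol(tom))
    d <- 1 - tom
    hc <- stats::hclust(stats::as.dist(d), method = "average")
    # guard against floating-point jitter in the merge heights
    hc$height <- cummax(round(hc$height, 12))
    cl <- stats::cutree(hc, h = cutHeight)
    sizes <- table(cl)
    small <- as.integer(names(sizes)[sizes < minModuleSize])
    cl[cl %in% small] <- 0L
    keep <- setdiff(unique(cl), 0L)
    if (length(keep)) {
        nm <- rownames(tom)
        key <- vapply(keep, function(m) {
            members <- which(cl == m)
            first <- if (!is.null(nm)) min(nm[members]) else
                as.character(min(members))
            first
        }, character(1))
        ord <- order(-as.integer(sizes[as.character(keep)]), key)
        newLab <- integer(max(keep))
        newLab[keep[ord]] <- seq_along(keep)
        cl[cl != 0L] <- newLab[cl[cl != 0L]]
    }
    out <- as.integer(cl)
    names(out) <- rownames(tom)
    out
}

#' Weighted co-expression network and modules in one step
#'
#' Pearson correlation across samples, unsigned soft-threshold adjacency,
#' topological overlap, and static-cut module detection. If `beta` is `NULL`
#' it is chosen with [selectSoftPower()].
#'
#' @param x samples x genes numeric matrix (columns named by gene).
#' @param beta soft-threshold power, or `NULL` to select automatically.
#' @param cutHeight,minModuleSize see [detectModules()].
#' @param signed see [adjacencyFromCorr()].
#' @return a [CoexpressionResult-class].
#' @export
coexpressionModules <- function(x, beta = NULL, cutHeight = 0.99,
                                minModuleSize = 10, signed = FALSE) {
    stopifnot(is.matrix(x), !is.null(colnames(x)))
    corr <- stats::cor(x)
    fit <- data.frame(power = numeric(), r2 = numeric())
    if (is.null(beta)) {
        sel <- selectSoftPower(corr)
        beta <- sel$power
        fit <- sel$fit
    }
    a <- adjacencyFromCorr(corr, beta, signed)
    tom <- tomFromAdjacency(a)
    modules <- detectModules(tom, cutHeight, minModuleSize)
    methods::new("CoexpressionResult", power = as.numeric(beta),
                 adjacency = a, tom = tom, modules = modules,
                 scaleFreeFit = fit)
}

#' Count detected modules per biotype
#'
#' Number of non-zero module labels containing at least `minModuleSize`
#' genes of each biotype. On a biotype-stratified run (all genes of one
#' biotype) this is simply the number of detected modules for that biotype.
#'
#' @param labels named integer module labels (see [detectModules()]).
#' @param annotations named character vector gene_id -> biotype.
#' @param minModuleSize minimum genes of the biotype per module (default 10).
#' @return data.frame `biotype`, `modules`.
#' @export
countModulesByBiotype <- function(labels, annotations, minModuleSize = 10) {
    bt <- annotations[names(labels)]
    bts <- sort(unique(bt[!is.na(bt)]))
    res <- vapply(bts, function(b) {
        lab <- labels[!is.na(bt) & bt == b & labels != 0L]
        if (!length(lab)) return(0L)
        sum(table(lab) >= minModuleSize)
    }, integer(1))
    data.frame(biotype = bts, modules = as.integer(res),
               row.names = NULL, stringsAsFactors = FALSE)
}
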